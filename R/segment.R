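#' Background subtraction and denoising
#'
#' Estimates a slowly varying background with a large-window median filter
#' (window well above the cell diameter, so whole cells are rejected from the
#' estimate), subtracts it, clamps at zero, and optionally applies a light
#' Gaussian denoise. A constant image maps to all zeros.
#'
#' @param image 2-D non-negative intensity matrix.
#' @param radius median-filter radius in pixels; should exceed the cell
#'   diameter.
#' @param smooth_sigma Gaussian denoise sigma (0 disables).
#' @return background-subtracted non-negative matrix, same shape.
#' @export
enhance <- function(image, radius = 25, smooth_sigma = 0) {
  stopifnot(is.matrix(image), all(image >= 0))
  top <- max(image, 1)
  bg <- as.matrix(EBImage::medianFilter(image / top, radius)) * top
  out <- pmax(image - bg, 0)
  if (smooth_sigma > 0) out <- pmax(as.matrix(EBImage::gblur(out, smooth_sigma)), 0)
  out
}

#' Gaussian-mixture foreground detection
#'
#' Fits a mixture of `n_components` Gaussians to per-pixel multichannel
#' log-intensity vectors (EM on a deterministic pixel subsample, then
#' classification of every pixel). The lowest-mean component - plus any
#' component whose mean lies within `merge_sd` background standard deviations
#' of it in every channel - is treated as background; pixels assigned to the
#' remaining brighter components form the foreground mask.
#'
#' @param channels a single intensity matrix or a list of matrices with
#'   identical shape.
#' @param n_components number of mixture components (default 3: background,
#'   dim debris, bright cells).
#' @param subsample maximum number of pixels used for the EM fit.
#' @param merge_sd background-merging distance in background SDs.
#' @param seed seed for the pixel subsample; the result is deterministic
#'   given it.
#' @return logical matrix, `TRUE` on foreground.
#' @export
detect_foreground_gmm <- function(channels, n_components = 3, subsample = 20000,
                                  merge_sd = 3, seed = 1) {
  if (is.matrix(channels)) channels <- list(channels)
  dm <- dim(channels[[1]])
  if (!all(vapply(channels, function(m) identical(dim(m), dm), logical(1))))
    abort("all channels must share one shape")
  x <- do.call(cbind, lapply(channels, function(m) log1p(as.numeric(m))))
  if (all(apply(x, 2, stats::sd) < 1e-10)) {
    warn("degenerate input (zero variance); returning all-background mask")
    return(matrix(FALSE, dm[1], dm[2]))
  }
  n <- nrow(x)
  idx <- withr::with_seed(seed, sample.int(n, min(subsample, n)))
  model_names <- if (ncol(x) == 1) "V" else "VVI"
  mclustBIC <- mclust::mclustBIC # Mclust() resolves this in the caller frame
  # conjugate prior regularises component covariances: background pixels can
  # sit at an exact point mass (e.g. all zero after background subtraction)
  fit <- withr::with_seed(seed, suppressWarnings(
    mclust::Mclust(x[idx, , drop = FALSE], G = n_components,
                   modelNames = model_names,
                   prior = mclust::priorControl(), verbose = FALSE)
  ))
  if (is.null(fit))
    fit <- withr::with_seed(seed, suppressWarnings(
      mclust::Mclust(x[idx, , drop = FALSE], G = seq_len(n_components),
                     prior = mclust::priorControl(), verbose = FALSE)
    ))
  if (is.null(fit)) {
    warn("mixture fit failed; returning all-background mask")
    return(matrix(FALSE, dm[1], dm[2]))
  }
  n_components <- fit$G
  cls <- stats::predict(fit, newdata = x)$classification
  mu <- matrix(fit$parameters$mean, ncol = n_components) # d x G
  bg <- which.min(colMeans(mu))
  sig <- fit$parameters$variance$sigma
  bg_sd <- if (length(dim(sig)) == 3) sqrt(diag(as.matrix(sig[, , bg]))) else sqrt(sig[bg])
  bg_set <- which(apply(abs(mu - mu[, bg]) <= merge_sd * bg_sd + 1e-12, 2, all))
  matrix(!(cls %in% bg_set), dm[1], dm[2])
}

# square max filter by iterated shifts; used for local-maximum seed detection
max_filter <- function(m, r) {
  out <- m
  nr <- nrow(m)
  for (k in seq_len(r)) {
    out[seq_len(nr - k), ] <- pmax(out[seq_len(nr - k), ], m[(k + 1):nr, ])
    out[(k + 1):nr, ] <- pmax(out[(k + 1):nr, ], m[seq_len(nr - k), ])
  }
  m2 <- out
  nc <- ncol(m)
  for (k in seq_len(r)) {
    out[, seq_len(nc - k)] <- pmax(out[, seq_len(nc - k)], m2[, (k + 1):nc])
    out[, (k + 1):nc] <- pmax(out[, (k + 1):nc], m2[, seq_len(nc - k)])
  }
  out
}

empty_label_maps <- function(dm) {
  z <- matrix(0L, dm[1], dm[2])
  structure(list(cell_labels = z, nucleus_labels = z), class = "label_maps")
}

# relabel both maps consecutively from 1 in scan order of the cell map,
# keeping only labels with non-empty cell AND nucleus regions
relabel_maps <- function(cell, nucleus, keep = NULL) {
  ids <- unique(cell[cell > 0])           # scan order of the stored array
  ids <- ids[ids %in% unique(nucleus[nucleus > 0])]
  if (!is.null(keep)) ids <- ids[ids %in% keep]
  lut <- integer(max(c(cell, nucleus, 1L)))
  lut[ids] <- seq_along(ids)
  cell2 <- matrix(0L, nrow(cell), ncol(cell))
  nuc2 <- cell2
  pos <- cell > 0
  cell2[pos] <- lut[cell[pos]]
  pos <- nucleus > 0
  nuc2[pos] <- lut[nucleus[pos]]
  structure(list(cell_labels = cell2, nucleus_labels = nuc2),
            class = "label_maps")
}

#' Seeded cross-channel watershed segmentation
#'
#' Detects nuclei on the (smoothed) nuclear channel - local maxima with a
#' minimum separation, grown over the thresholded nuclear mask - and uses
#' them as seeds for watershed-style region growing over the foreground mask
#' on a topography built jointly from both channels (inverted sum of
#' min-max-normalized smoothed channels). Produces matched cell and nucleus
#' label maps: nucleus pixels of label k are a subset of cell pixels of
#' label k, and labels are consecutive from 1.
#'
#' @param nuclear,reporter enhanced intensity matrices of identical shape.
#' @param mask logical foreground mask from [detect_foreground_gmm()].
#' @param min_seed_distance minimum separation between nucleus seeds, pixels.
#' @param seed_smooth_sigma Gaussian sigma applied to the nuclear channel
#'   before maximum detection.
#' @param topo_sigma Gaussian sigma used when building the watershed
#'   topography.
#' @param lambda regularisation of the region-growing metric (small values
#'   follow image boundaries, large values approach a Voronoi split).
#' @return a `label_maps` object: list of integer matrices `cell_labels` and
#'   `nucleus_labels` (0 = background).
#' @export
segment_cells <- function(nuclear, reporter, mask,
                          min_seed_distance = 7, seed_smooth_sigma = 2,
                          topo_sigma = 2, lambda = 1e-4) {
  dm <- dim(nuclear)
  if (!any(mask)) return(empty_label_maps(dm))
  nsm <- as.matrix(EBImage::gblur(nuclear, seed_smooth_sigma))
  rng <- range(nsm)
  if (diff(rng) < 1e-10) return(empty_label_maps(dm))
  n01 <- (nsm - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(n01))
  nuclear_mask <- n01 > th & mask
  if (!any(nuclear_mask)) return(empty_label_maps(dm))
  maxima <- (nsm == max_filter(nsm, min_seed_distance)) & nuclear_mask
  if (!any(maxima)) return(empty_label_maps(dm))
  seeds <- EBImage::bwlabel(maxima)
  nucleus_labels <- EBImage::imageData(
    EBImage::propagate(nsm, seeds, mask = nuclear_mask, lambda = lambda))
  sm <- function(ch) {
    s <- as.matrix(EBImage::gblur(ch, topo_sigma))
    r <- range(s)
    if (diff(r) < 1e-10) matrix(0, dm[1], dm[2]) else (s - r[1]) / diff(r)
  }
  topo <- sm(nuclear) + sm(reporter)
  topo <- max(topo) - topo
  cell_labels <- EBImage::imageData(
    EBImage::propagate(topo, nucleus_labels, mask = mask, lambda = lambda))
  # enforce nucleus containment before relabeling
  nucleus_labels[nucleus_labels != cell_labels] <- 0L
  relabel_maps(matrix(as.integer(cell_labels), dm[1], dm[2]),
               matrix(as.integer(nucleus_labels), dm[1], dm[2]))
}

#' Morphological refinement rules
#'
#' Bounds on per-object attributes used by [refine()]. Defaults are
#' calibrated to the simulator's default geometry (cell radius ~10 px,
#' nucleus fraction 0.55); the upstream assay software publishes no rule set,
#' so every bound is configurable.
#'
#' @param min_cell_area,max_cell_area cell area bounds, pixels.
#' @param min_nucleus_area,max_nucleus_area nucleus area bounds, pixels.
#' @param max_eccentricity maximum ellipse eccentricity (0 = circle).
#' @param min_solidity minimum area / convex-hull-area ratio.
#' @param nucleus_cell_ratio allowed (min, max) nucleus-to-cell area ratio.
#' @return a `morphology_rules` list.
#' @export
morphology_rules <- function(min_cell_area = 40, max_cell_area = 6000,
                             min_nucleus_area = 20, max_nucleus_area = 2500,
                             max_eccentricity = 0.95, min_solidity = 0.4,
                             nucleus_cell_ratio = c(0.05, 1)) {
  rules <- list(min_cell_area = min_cell_area, max_cell_area = max_cell_area,
                min_nucleus_area = min_nucleus_area,
                max_nucleus_area = max_nucleus_area,
                max_eccentricity = max_eccentricity,
                min_solidity = min_solidity,
                nucleus_cell_ratio = nucleus_cell_ratio)
  if (rules$min_cell_area >= rules$max_cell_area ||
      rules$min_nucleus_area >= rules$max_nucleus_area ||
      rules$nucleus_cell_ratio[1] >= rules$nucleus_cell_ratio[2])
    abort("each rule's min bound must be below its max bound",
          class = "ncrscreen_config_error")
  structure(rules, class = "morphology_rules")
}

# polygon area of the convex hull of an object's pixel centres, with a
# half-perimeter correction so a digitised disk gets solidity ~ 1
convex_area <- function(rows, cols) {
  if (length(rows) < 3) return(length(rows))
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3) return(length(rows))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  j <- c(2:n, 1)
  area <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
  perim <- sum(sqrt(rowSums((hp - hp[j, , drop = FALSE])^2)))
  area + perim / 2 + 1
}

#' Per-object morphological features
#'
#' @param maps a `label_maps` object.
#' @return tibble with one row per label: `label`, `centroid_row`,
#'   `centroid_col`, `cell_area`, `nucleus_area`, `eccentricity`, `solidity`.
#' @export
label_features <- function(maps) {
  cl <- maps$cell_labels
  n_obj <- max(cl)
  if (n_obj == 0)
    return(tibble::tibble(label = integer(0), centroid_row = numeric(0),
                          centroid_col = numeric(0), cell_area = integer(0),
                          nucleus_area = integer(0), eccentricity = numeric(0),
                          solidity = numeric(0)))
  idx <- which(cl > 0)
  lab <- cl[idx]
  rows <- (idx - 1L) %% nrow(cl) + 1L
  cols <- (idx - 1L) %/% nrow(cl) + 1L
  cell_area <- tabulate(lab, n_obj)
  nucleus_area <- tabulate(maps$nucleus_labels[maps$nucleus_labels > 0], n_obj)
  cr <- rowsum(as.numeric(rows), lab)[, 1] / cell_area
  cc <- rowsum(as.numeric(cols), lab)[, 1] / cell_area
  mom <- EBImage::computeFeatures.moment(cl)
  ecc <- rep(0, n_obj)
  ecc[seq_len(nrow(mom))] <- mom[, "m.eccentricity"]
  sol <- vapply(seq_len(n_obj), function(k) {
    sel <- lab == k
    cell_area[k] / max(convex_area(rows[sel], cols[sel]), cell_area[k])
  }, numeric(1))
  tibble::tibble(label = seq_len(n_obj), centroid_row = cr, centroid_col = cc,
                 cell_area = cell_area, nucleus_area = nucleus_area,
                 eccentricity = ecc, solidity = sol)
}

#' Rule-based morphological refinement
#'
#' Removes objects violating any morphology rule (the cell and its nucleus
#' are removed together) and relabels survivors consecutively from 1 in scan
#' order.
#'
#' @param maps a `label_maps` object.
#' @param rules a [morphology_rules()] list.
#' @return refined `label_maps`.
#' @export
refine <- function(maps, rules = morphology_rules()) {
  feats <- label_features(maps)
  if (nrow(feats) == 0) return(maps)
  ratio <- feats$nucleus_area / feats$cell_area
  ok <- feats$cell_area >= rules$min_cell_area &
    feats$cell_area <= rules$max_cell_area &
    feats$nucleus_area >= rules$min_nucleus_area &
    feats$nucleus_area <= rules$max_nucleus_area &
    feats$eccentricity <= rules$max_eccentricity &
    feats$solidity >= rules$min_solidity &
    ratio >= rules$nucleus_cell_ratio[1] &
    ratio <= rules$nucleus_cell_ratio[2]
  relabel_maps(maps$cell_labels, maps$nucleus_labels,
               keep = feats$label[ok])
}

#' Write label maps and the per-object feature CSV
#'
#' @param maps a `label_maps` object.
#' @param dir output directory.
#' @param name filename stem (e.g. the well id).
#' @return `dir`, invisibly.
#' @export
write_labels <- function(maps, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("cell_labels", "nucleus_labels")) {
    EBImage::writeImage(EBImage::Image(t(maps[[ch]]) / 65535),
                        file.path(dir, sprintf("%s_%s.tif", name, ch)),
                        type = "tiff", bits.per.sample = 16L)
  }
  readr::write_csv(label_features(maps),
                   file.path(dir, sprintf("%s_objects.csv", name)))
  invisible(dir)
}
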