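#' Configuration for the synthetic plate-imaging simulator
#'
#' Builds the parameter set for [generate_plate()]. The simulator emulates a
#' fixed-endpoint nuclear translocation reporter assay: adherent cells carry a
#' nuclear stain (one channel) and, if transfected, a fluorescent pathway
#' reporter (second channel) whose nuclear-to-cytoplasmic ratio (NCR) encodes
#' pathway activation. Each condition is imaged in `wells_per_condition`
#' replicate wells (six, matching the assay design) and per-cell NCRs are
#' drawn from a condition-specific log-normal distribution.
#'
#' Cells are circular disks with a concentric nuclear disk; cells may touch
#' (centres are kept `min_separation` apart, close enough for neighbouring
#' cell bodies to overlap while nuclei stay separable). The nuclear stain
#' occupies the nucleus only; the reporter of a transfected cell is
#' partitioned between nucleus and cytoplasmic annulus so that the ratio of
#' their mean intensities equals the sampled `true_ncr` exactly before
#' background, blur and noise. Signal is blurred with a Gaussian PSF, then
#' additive Gaussian read noise is applied and intensities are clipped to the
#' 16-bit range.
#'
#' @param image_size integer `(height, width)` in pixels.
#' @param cells_per_well cells planted per well.
#' @param cell_radius_mean,cell_radius_sd cell radius distribution, pixels.
#' @param nucleus_radius_fraction nucleus radius as a fraction of the cell
#'   radius; must lie strictly in (0, 1).
#' @param conditions named list; each element is `c(median =, dispersion =)`
#'   giving the log-normal NCR median and log-scale dispersion for one
#'   condition.
#' @param transfection_fraction fraction of cells expressing the reporter.
#' @param background_level constant background intensity added to both
#'   channels.
#' @param noise_sd standard deviation of additive Gaussian read noise.
#' @param blur_sigma Gaussian PSF sigma in pixels (0 disables blurring).
#' @param nuclear_intensity nuclear-stain amplitude above background.
#' @param reporter_level cytoplasmic reporter amplitude of a transfected cell;
#'   its nuclear amplitude is `true_ncr * reporter_level`.
#' @param wells_per_condition replicate wells per condition (default 6).
#' @param n_debris bright sub-cellular debris specks planted per well (appear
#'   in both channels; absent from the ground truth).
#' @param debris_radius debris speck radius, pixels.
#' @param min_separation minimum distance between cell centres, pixels;
#'   default `1.3 * cell_radius_mean`.
#' @param seed integer seed; the whole plate is reproducible from it.
#' @return a `sim_config` list.
#' @seealso [generate_plate()]
#' @export
sim_config <- function(image_size = c(640L, 640L),
                       cells_per_well = 400L,
                       cell_radius_mean = 10,
                       cell_radius_sd = 1,
                       nucleus_radius_fraction = 0.55,
                       conditions = list(WT = c(median = 1, dispersion = 0.1)),
                       transfection_fraction = 0.5,
                       background_level = 100,
                       noise_sd = 5,
                       blur_sigma = 1,
                       nuclear_intensity = 1200,
                       reporter_level = 400,
                       wells_per_condition = 6L,
                       n_debris = 0L,
                       debris_radius = 2,
                       min_separation = NULL,
                       seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size),
    cells_per_well = as.integer(cells_per_well),
    cell_radius_mean = cell_radius_mean,
    cell_radius_sd = cell_radius_sd,
    nucleus_radius_fraction = nucleus_radius_fraction,
    conditions = conditions,
    transfection_fraction = transfection_fraction,
    background_level = background_level,
    noise_sd = noise_sd,
    blur_sigma = blur_sigma,
    nuclear_intensity = nuclear_intensity,
    reporter_level = reporter_level,
    wells_per_condition = as.integer(wells_per_condition),
    n_debris = as.integer(n_debris),
    debris_radius = debris_radius,
    min_separation = min_separation %||% (1.3 * cell_radius_mean),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$nucleus_radius_fraction <= 0 || cfg$nucleus_radius_fraction >= 1)
    abort("config error: nucleus_radius_fraction must lie strictly in (0, 1)",
          class = "ncrscreen_config_error")
  if (cfg$cells_per_well < 0)
    abort("config error: cells_per_well must be >= 0",
          class = "ncrscreen_config_error")
  if (cfg$wells_per_condition < 1)
    abort("config error: wells_per_condition must be >= 1",
          class = "ncrscreen_config_error")
  if (cfg$transfection_fraction < 0 || cfg$transfection_fraction > 1)
    abort("config error: transfection_fraction must lie in [0, 1]",
          class = "ncrscreen_config_error")
  if (length(cfg$conditions) < 1 || is.null(names(cfg$conditions)))
    abort("config error: conditions must be a named list",
          class = "ncrscreen_config_error")
  invisible(cfg)
}

# 96-well identifiers A01..H12 in row-major plate order
well_ids_96 <- function(n) {
  ids <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  if (n > length(ids)) ids <- c(ids, sprintf("X%03d", seq_len(n - length(ids))))
  ids[seq_len(n)]
}

# linear pixel indices of a disk, clipped to the canvas
disk_pixels <- function(dim, center, radius) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(dim[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(dim[2], ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  inside <- outer((rows - center[1])^2, (cols - center[2])^2, "+") <= radius^2
  idx <- outer(rows, (cols - 1L) * dim[1], "+")
  idx[inside]
}

#' Render one cell onto a two-channel canvas
#'
#' Adds the nuclear-stain disk and, for a transfected cell, the reporter
#' signal partitioned between nucleus and cytoplasmic annulus in the ratio
#' `true_ncr`, to the noise-free canvas. Overlapping cells sum additively;
#' disks are clipped at the canvas border.
#'
#' @param canvas list with matrices `nuclear` and `reporter` (same shape).
#' @param cell one-row data frame or list with `center_row`, `center_col`,
#'   `cell_radius`, `nucleus_radius`, `true_ncr`, `transfected`.
#' @param config a [sim_config()].
#' @return the updated canvas list.
#' @export
render_cell <- function(canvas, cell, config) {
  dm <- dim(canvas$nuclear)
  ctr <- c(cell$center_row, cell$center_col)
  nuc <- disk_pixels(dm, ctr, cell$nucleus_radius)
  canvas$nuclear[nuc] <- canvas$nuclear[nuc] + config$nuclear_intensity
  if (isTRUE(cell$transfected)) {
    cellpx <- disk_pixels(dm, ctr, cell$cell_radius)
    cyt <- setdiff(cellpx, nuc)
    canvas$reporter[nuc] <- canvas$reporter[nuc] +
      cell$true_ncr * config$reporter_level
    canvas$reporter[cyt] <- canvas$reporter[cyt] + config$reporter_level
  }
  canvas
}

# sample cell centres with a minimum pairwise separation (rejection sampling)
sample_centers <- function(n, dim, margin, min_sep) {
  centers <- matrix(numeric(0), ncol = 2)
  attempts <- 0L
  while (nrow(centers) < n && attempts < 400L * max(n, 1L)) {
    attempts <- attempts + 1L
    cand <- c(runif(1, 1 + margin, dim[1] - margin),
              runif(1, 1 + margin, dim[2] - margin))
    if (nrow(centers) == 0 ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= min_sep^2)
      centers <- rbind(centers, cand)
  }
  if (nrow(centers) < n)
    abort("could not place all cells: lower cells_per_well or min_separation")
  centers
}

simulate_well <- function(well_id, condition_id, cond, cfg) {
  dm <- cfg$image_size
  canvas <- list(nuclear = matrix(0, dm[1], dm[2]),
                 reporter = matrix(0, dm[1], dm[2]))
  n <- cfg$cells_per_well
  gt <- tibble::tibble(
    well_id = character(0), condition_id = character(0), cell_id = integer(0),
    center_row = numeric(0), center_col = numeric(0), cell_radius = numeric(0),
    nucleus_radius = numeric(0), true_ncr = numeric(0), transfected = logical(0)
  )
  if (n > 0) {
    margin <- cfg$cell_radius_mean + 3 * cfg$cell_radius_sd + 2
    centers <- sample_centers(n, dm, margin, cfg$min_separation)
    radii <- pmax(3, rnorm(n, cfg$cell_radius_mean, cfg$cell_radius_sd))
    gt <- tibble::tibble(
      well_id = well_id, condition_id = condition_id, cell_id = seq_len(n),
      center_row = centers[, 1], center_col = centers[, 2],
      cell_radius = radii,
      nucleus_radius = cfg$nucleus_radius_fraction * radii,
      true_ncr = rlnorm(n, meanlog = log(cond[["median"]]),
                        sdlog = cond[["dispersion"]]),
      transfected = runif(n) < cfg$transfection_fraction
    )
    for (i in seq_len(n)) canvas <- render_cell(canvas, gt[i, ], cfg)
  }
  if (cfg$n_debris > 0) {
    for (k in seq_len(cfg$n_debris)) {
      ctr <- c(runif(1, 2, dm[1] - 1), runif(1, 2, dm[2] - 1))
      px <- disk_pixels(dm, ctr, cfg$debris_radius)
      canvas$nuclear[px] <- canvas$nuclear[px] + cfg$nuclear_intensity
      canvas$reporter[px] <- canvas$reporter[px] + cfg$reporter_level
    }
  }
  canvas$nuclear <- canvas$nuclear + cfg$background_level
  canvas$reporter <- canvas$reporter + cfg$background_level
  if (cfg$blur_sigma > 0) {
    canvas$nuclear <- as.matrix(EBImage::gblur(canvas$nuclear, cfg$blur_sigma))
    canvas$reporter <- as.matrix(EBImage::gblur(canvas$reporter, cfg$blur_sigma))
  }
  if (cfg$noise_sd > 0) {
    canvas$nuclear <- canvas$nuclear + rnorm(length(canvas$nuclear), 0, cfg$noise_sd)
    canvas$reporter <- canvas$reporter + rnorm(length(canvas$reporter), 0, cfg$noise_sd)
  }
  canvas$nuclear <- round(pmin(pmax(canvas$nuclear, 0), 65535))
  canvas$reporter <- round(pmin(pmax(canvas$reporter, 0), 65535))
  list(well_id = well_id, condition_id = condition_id,
       nuclear = canvas$nuclear, reporter = canvas$reporter, ground_truth = gt)
}

#' Generate a ground-truthed synthetic plate
#'
#' Simulates `wells_per_condition` two-channel wells for every condition in
#' the configuration. The result is bit-reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list of class `ncr_plate` with elements
#'   * `wells`: named list; each element has `well_id`, `condition_id` and the
#'     integer intensity matrices `nuclear` and `reporter`;
#'   * `layout`: tibble (`well_id`, `condition_id`);
#'   * `ground_truth`: tibble of planted cells (centre, radii, `true_ncr`,
#'     `transfected`);
#'   * `config`: the configuration used.
#' @examples
#' cfg <- sim_config(image_size = c(96, 96), cells_per_well = 5,
#'                   wells_per_condition = 1, seed = 7)
#' plate <- generate_plate(cfg)
#' plate$layout
#' @export
generate_plate <- function(config) {
  validate_sim_config(config)
  cond_ids <- names(config$conditions)
  n_wells <- length(cond_ids) * config$wells_per_condition
  ids <- well_ids_96(n_wells)
  layout <- tibble::tibble(
    well_id = ids,
    condition_id = rep(cond_ids, each = config$wells_per_condition)
  )
  wells <- withr::with_seed(config$seed, {
    purrr::map2(layout$well_id, layout$condition_id, function(w, cid) {
      simulate_well(w, cid, config$conditions[[cid]], config)
    })
  })
  names(wells) <- layout$well_id
  gt <- purrr::map_dfr(wells, "ground_truth")
  wells <- purrr::map(wells, function(w) w[c("well_id", "condition_id",
                                             "nuclear", "reporter")])
  structure(list(wells = wells, layout = layout, ground_truth = gt,
                 config = config),
            class = "ncr_plate")
}

#' Write a simulated plate to disk
#'
#' Writes one 16-bit TIFF per well per channel
#' (`<plate>_<well>_<channel>.tif`), a plate-layout CSV and a ground-truth
#' CSV, in the layout consumed by [read_plate()].
#'
#' @param plate an `ncr_plate` from [generate_plate()].
#' @param dir output directory (created if needed).
#' @param plate_name filename prefix.
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir, plate_name = "plate01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in plate$wells) {
    for (ch in c("nuclear", "reporter")) {
      f <- file.path(dir, sprintf("%s_%s_%s.tif", plate_name, w$well_id, ch))
      EBImage::writeImage(EBImage::Image(t(w[[ch]]) / 65535),
                          f, type = "tiff", bits.per.sample = 16L)
    }
  }
  readr::write_csv(plate$layout, file.path(dir, paste0(plate_name, "_layout.csv")))
  readr::write_csv(plate$ground_truth,
                   file.path(dir, paste0(plate_name, "_ground_truth.csv")))
  invisible(dir)
}

#' Read a plate written by [write_plate()]
#'
#' @param dir directory containing the TIFFs and layout CSV.
#' @param plate_name filename prefix used when writing.
#' @return an `ncr_plate` list (without `config`).
#' @export
read_plate <- function(dir, plate_name = "plate01") {
  layout <- readr::read_csv(file.path(dir, paste0(plate_name, "_layout.csv")),
                            col_types = "cc")
  gt_path <- file.path(dir, paste0(plate_name, "_ground_truth.csv"))
  gt <- if (file.exists(gt_path))
    readr::read_csv(gt_path, show_col_types = FALSE) else NULL
  wells <- purrr::map2(layout$well_id, layout$condition_id, function(w, cid) {
    chans <- purrr::map(c(nuclear = "nuclear", reporter = "reporter"), function(ch) {
      f <- file.path(dir, sprintf("%s_%s_%s.tif", plate_name, w, ch))
      m <- EBImage::imageData(EBImage::readImage(f))
      round(t(m) * 65535)
    })
    list(well_id = w, condition_id = cid,
         nuclear = chans$nuclear, reporter = chans$reporter)
  })
  names(wells) <- layout$well_id
  structure(list(wells = wells, layout = layout, ground_truth = gt),
            class = "ncr_plate")
}
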