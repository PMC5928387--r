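#' Per-cell nuclear-to-cytoplasmic reporter ratios
#'
#' For every segmented cell, computes the mean reporter intensity over the
#' nucleus pixels and over the cytoplasm (cell minus nucleus, strict set
#' difference), and their ratio (NCR). Cells whose cytoplasm is empty or
#' whose cytoplasmic mean does not exceed `epsilon` are excluded with a
#' reason code instead of producing an unbounded ratio. Each cell is gated as
#' transfected when its whole-cell mean reporter intensity exceeds the
#' background mean plus `gate_k` background standard deviations; background
#' statistics are estimated from pixels outside all cells unless supplied.
#'
#' Compartment boundaries carry partial-volume error: the optical blur mixes
#' nucleus with cytoplasm at the nuclear rim and cytoplasm with background at
#' the cell edge, and the detected nucleus tends to overshoot the true one.
#' Guard rings therefore exclude boundary pixels from the compartment means:
#' the nuclear mean is taken over the nucleus eroded by `nucleus_guard`
#' pixels, and the cytoplasmic mean excludes a `cyto_nucleus_guard`-pixel
#' ring around the nucleus and a `boundary_guard`-pixel ring along the
#' cell/background edge. Whenever a guard would empty a compartment it falls
#' back to the unguarded region, so small hand-built objects are unaffected.
#'
#' @param maps a `label_maps` object from [segment_cells()]/[refine()].
#' @param reporter reporter-channel intensity matrix (enhanced).
#' @param well_id optional well identifier attached to each row.
#' @param epsilon minimum admissible cytoplasmic mean (intensity units).
#' @param gate_k transfection gate width in background SDs.
#' @param background optional `c(mean, sd)` overriding the estimate.
#' @param nucleus_guard erosion of the nucleus before the nuclear mean, px.
#' @param cyto_nucleus_guard ring around the nucleus excluded from the
#'   cytoplasm, px (0 disables; 1 is the classic bleed-through ring).
#' @param boundary_guard ring along the cell/background boundary excluded
#'   from the cytoplasm, px.
#' @return tibble with one row per cell: `well_id`, `label`, `nuclear_mean`,
#'   `cytoplasm_mean`, `cell_mean`, `ncr`, `transfected`, `excluded_reason`
#'   (`NA` for usable cells).
#' @export
quantify_cells <- function(maps, reporter, well_id = NA_character_,
                           epsilon = 1, gate_k = 3, background = NULL,
                           nucleus_guard = 2, cyto_nucleus_guard = 1,
                           boundary_guard = 2) {
  cl <- maps$cell_labels
  nl <- maps$nucleus_labels
  n_obj <- max(cl)
  empty <- tibble::tibble(well_id = character(0), label = integer(0),
                          nuclear_mean = numeric(0), cytoplasm_mean = numeric(0),
                          cell_mean = numeric(0), ncr = numeric(0),
                          transfected = logical(0), excluded_reason = character(0))
  if (n_obj == 0) return(empty)
  grow <- function(mask, px, op) {
    if (px <= 0) return(mask)
    EBImage::imageData(op(EBImage::Image(mask),
                          EBImage::makeBrush(2L * px + 1L, "box"))) > 0
  }
  nuc_core <- grow(nl > 0, nucleus_guard, EBImage::erode)
  nuc_halo <- grow(nl > 0, cyto_nucleus_guard, EBImage::dilate)
  bg_halo <- grow(cl == 0, boundary_guard, EBImage::dilate)
  sum_by <- function(idx, lab_map) {
    out <- numeric(n_obj)
    cnt <- integer(n_obj)
    lab <- lab_map[idx]
    if (length(lab)) {
      s <- rowsum(reporter[idx], lab)
      out[as.integer(rownames(s))] <- s[, 1]
      cnt <- tabulate(lab, n_obj)
    }
    list(sum = out, n = cnt)
  }
  nuc_all <- sum_by(which(nl > 0), nl)
  nuc_g <- sum_by(which(nl > 0 & nuc_core), nl)
  cell_all <- sum_by(which(cl > 0), cl)
  cyt_all <- sum_by(which(cl > 0 & nl == 0), cl)
  cyt_g <- sum_by(which(cl > 0 & nl == 0 & !nuc_halo & !bg_halo), cl)
  pick <- function(g, all) {
    use <- g$n > 0
    list(mean = ifelse(use, g$sum / pmax(g$n, 1L),
                       ifelse(all$n > 0, all$sum / pmax(all$n, 1L), NA_real_)),
         n = ifelse(use, g$n, all$n))
  }
  nuc <- pick(nuc_g, nuc_all)
  cyt <- pick(cyt_g, cyt_all)
  nuclear_mean <- nuc$mean
  cytoplasm_mean <- cyt$mean
  nuc_n <- nuc_all$n
  cyt_n <- cyt_all$n
  cell_mean <- ifelse(cell_all$n > 0, cell_all$sum / pmax(cell_all$n, 1L), NA_real_)
  if (is.null(background)) {
    bgpx <- reporter[cl == 0]
    background <- c(mean(bgpx), stats::sd(bgpx))
  }
  gate <- background[1] + gate_k * background[2]
  excluded <- dplyr::case_when(
    nuc_n == 0 ~ "empty_nucleus",
    cyt_n == 0 ~ "empty_cytoplasm",
    cytoplasm_mean <= epsilon ~ "cytoplasm_below_epsilon",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    well_id = well_id, label = seq_len(n_obj),
    nuclear_mean = nuclear_mean, cytoplasm_mean = cytoplasm_mean,
    cell_mean = cell_mean,
    ncr = ifelse(is.na(excluded), nuclear_mean / cytoplasm_mean, NA_real_),
    transfected = !is.na(cell_mean) & cell_mean > gate,
    excluded_reason = excluded
  )
}

#' NCR of a single segmented cell
#'
#' Convenience wrapper around [quantify_cells()] for one label.
#'
#' @inheritParams quantify_cells
#' @param label the cell label to quantify.
#' @param ... further arguments passed to [quantify_cells()].
#' @return one-row tibble as in [quantify_cells()].
#' @export
compute_cell_ncr <- function(maps, reporter, label, ...) {
  cells <- quantify_cells(maps, reporter, ...)
  row <- cells[cells$label == label, ]
  if (nrow(row) == 0) abort(sprintf("label %s not present in the label maps", label))
  row
}

#' Re-gate cells as transfected with an explicit threshold
#'
#' @param cells tibble from [quantify_cells()].
#' @param threshold whole-cell mean reporter intensity gate; cells strictly
#'   above it are transfected. A gate of 0 passes every cell with positive
#'   signal.
#' @return `cells` with the `transfected` column recomputed.
#' @export
gate_transfected <- function(cells, threshold) {
  dplyr::mutate(cells, transfected = .data$cell_mean > threshold)
}

#' Well-level NCR: median over transfected cells
#'
#' The median NCR over the well's transfected (and non-excluded) cells is the
#' NCR of the condition in that well. Wells with fewer than `min_cells`
#' usable transfected cells are flagged invalid with a warning and excluded
#' downstream.
#'
#' @param cells tibble from [quantify_cells()] for one well.
#' @param min_cells minimum usable transfected cells for a valid well.
#' @return one-row tibble: `well_id`, `n_cells`, `median_ncr`, `valid`.
#' @export
well_ncr <- function(cells, min_cells = 50) {
  usable <- dplyr::filter(cells, .data$transfected, is.na(.data$excluded_reason))
  wid <- if (nrow(cells) > 0) cells$well_id[1] else NA_character_
  n <- nrow(usable)
  if (n < min_cells) {
    warn(sprintf("well %s has %d usable transfected cells (< %d); flagged invalid",
                 wid, n, min_cells))
    return(tibble::tibble(well_id = wid, n_cells = n,
                          median_ncr = NA_real_, valid = FALSE))
  }
  tibble::tibble(well_id = wid, n_cells = n,
                 median_ncr = median(usable$ncr), valid = TRUE)
}

#' Condition-level NCR: mean of well medians
#'
#' Averages the valid replicate-well medians of one condition. Six wells are
#' expected; three to five valid wells proceed with a warning, fewer than
#' three is an error.
#'
#' @param wells tibble of [well_ncr()] rows sharing one condition, with a
#'   `condition_id` column.
#' @param expected_wells replicate wells expected per condition.
#' @param min_wells minimum valid wells required.
#' @return one-row tibble: `condition_id`, `mean_ncr`, `sd_ncr`, `n_wells`,
#'   and `well_medians` (list column of the valid medians).
#' @export
condition_ncr <- function(wells, expected_wells = 6, min_wells = 3) {
  cid <- unique(wells$condition_id)
  if (length(cid) != 1)
    abort("all wells passed to condition_ncr must share one condition_id")
  ok <- wells[wells$valid %in% TRUE, ]
  if (nrow(ok) < min_wells)
    abort(sprintf("condition %s: only %d valid wells (minimum %d); invalid wells: %s",
                  cid, nrow(ok), min_wells,
                  paste(wells$well_id[!wells$valid], collapse = ", ")),
          class = "ncrscreen_too_few_wells")
  if (nrow(ok) < expected_wells)
    warn(sprintf("condition %s: %d valid wells (expected %d); proceeding",
                 cid, nrow(ok), expected_wells))
  tibble::tibble(condition_id = cid,
                 mean_ncr = mean(ok$median_ncr),
                 sd_ncr = stats::sd(ok$median_ncr),
                 n_wells = nrow(ok),
                 well_medians = list(ok$median_ncr))
}
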