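make_maps <- function(cell, nucleus) {
  structure(list(cell_labels = cell, nucleus_labels = nucleus),
            class = "label_maps")
}

one_cell_maps <- function(n = 40) {
  cl <- matrix(0L, n, n); nl <- matrix(0L, n, n)
  rows <- matrix(rep(seq_len(n), n), n); cols <- t(rows)
  d2 <- (rows - n / 2)^2 + (cols - n / 2)^2
  cl[d2 <= 144] <- 1L
  nl[d2 <= 36] <- 1L
  make_maps(cl, nl)
}

test_that("per-cell NCR is the ratio of compartment means", {
  maps <- one_cell_maps()
  uniform <- matrix(150, 40, 40)
  rec <- quantify_cells(maps, uniform, background = c(0, 1))
  expect_equal(rec$ncr, 1.0)

  img <- matrix(0, 40, 40)
  img[maps$cell_labels == 1] <- 100
  img[maps$nucleus_labels == 1] <- 200
  rec <- quantify_cells(maps, img, background = c(0, 1))
  expect_equal(rec$nuclear_mean, 200)
  expect_equal(rec$cytoplasm_mean, 100)
  expect_equal(rec$ncr, 2.0)

  single <- compute_cell_ncr(maps, img, label = 1, background = c(0, 1))
  expect_equal(single$ncr, 2.0)
  expect_error(compute_cell_ncr(maps, img, label = 9, background = c(0, 1)),
               "not present")
})

test_that("NCR is invariant to positive rescaling of the reporter channel", {
  maps <- one_cell_maps()
  img <- matrix(0, 40, 40)
  img[maps$cell_labels == 1] <- 80
  img[maps$nucleus_labels == 1] <- 260
  r1 <- quantify_cells(maps, img, background = c(0, 1))$ncr
  r2 <- quantify_cells(maps, img * 7.3, background = c(0, 1))$ncr
  expect_equal(r1, r2)
})

test_that("cells with empty or near-zero cytoplasm are excluded, not infinite", {
  cl <- matrix(0L, 20, 20); nl <- matrix(0L, 20, 20)
  cl[5:10, 5:10] <- 1L; nl[5:10, 5:10] <- 1L # nucleus fills the cell
  rec <- quantify_cells(make_maps(cl, nl), matrix(100, 20, 20),
                        background = c(0, 1))
  expect_equal(rec$excluded_reason, "empty_cytoplasm")
  expect_true(is.na(rec$ncr))

  maps <- one_cell_maps()
  dim_img <- matrix(0, 40, 40)
  dim_img[maps$nucleus_labels == 1] <- 50 # cytoplasm stays at 0 <= epsilon
  rec2 <- quantify_cells(maps, dim_img, background = c(0, 1))
  expect_equal(rec2$excluded_reason, "cytoplasm_below_epsilon")
  expect_true(is.na(rec2$ncr))
})

test_that("transfection gating matches the planted transfection fraction", {
  # non-touching cells so the gate, not watershed bleed, decides each call
  cfg <- test_sim_config(image_size = c(320L, 320L), cells_per_well = 40,
                         wells_per_condition = 1, min_separation = 24,
                         conditions = list(V = c(median = 2, dispersion = 0.1)))
  p <- generate_plate(cfg)
  seg <- segment_well(p$wells[[1]])
  cells <- quantify_cells(seg$maps, seg$reporter)
  frac <- mean(cells$transfected)
  planted <- mean(p$ground_truth$transfected)
  expect_lt(abs(frac - planted), 0.10)

  # degenerate gates
  expect_true(all(gate_transfected(cells, 0)$transfected |
                    is.na(cells$cell_mean)))
  expect_false(any(gate_transfected(cells, Inf)$transfected))
})

test_that("well medians are computed over transfected cells only", {
  cells <- tibble::tibble(
    well_id = "B02", label = 1:6,
    nuclear_mean = 1, cytoplasm_mean = 1, cell_mean = 1,
    ncr = c(1, 2, 3, 10, 50, 100),
    transfected = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    excluded_reason = NA_character_
  )
  expect_equal(well_ncr(cells, min_cells = 3)$median_ncr, 2)      # odd count
  cells$transfected[4] <- TRUE
  expect_equal(well_ncr(cells, min_cells = 3)$median_ncr, 2.5)    # even count
  expect_warning(w <- well_ncr(cells, min_cells = 50), "flagged invalid")
  expect_false(w$valid)
})

test_that("condition summaries average well medians and enforce the well minimum", {
  wells <- tibble::tibble(
    well_id = sprintf("A%02d", 1:6), condition_id = "VUS",
    n_cells = 100, median_ncr = c(1, 2, 3, 4, 5, 6), valid = TRUE
  )
  res <- condition_ncr(wells)
  expect_equal(res$mean_ncr, 3.5)
  expect_equal(res$well_medians[[1]], 1:6)

  flat <- dplyr::mutate(wells, median_ncr = 2)
  expect_equal(condition_ncr(flat)$mean_ncr, 2)
  expect_equal(condition_ncr(flat)$sd_ncr, 0)

  # order invariance
  expect_equal(condition_ncr(wells[sample(6), ])$mean_ncr, 3.5)

  expect_error(condition_ncr(wells[1:2, ]), class = "ncrscreen_too_few_wells")
  expect_warning(condition_ncr(wells[1:4, ]), "expected 6")
})

test_that("condition NCR is recovered within 10% across the assay range", {
  # parameter recovery at NCR medians 1 and 3 under default noise
  cfg <- test_sim_config(
    cells_per_well = 60,
    conditions = list(LOW = c(median = 1, dispersion = 0.1),
                      HIGH = c(median = 3, dispersion = 0.1)))
  p <- generate_plate(cfg)
  wells <- purrr::map_dfr(p$wells, function(w) {
    seg <- segment_well(w)
    cells <- quantify_cells(seg$maps, seg$reporter, well_id = w$well_id)
    out <- well_ncr(cells, min_cells = 10)
    out$condition_id <- w$condition_id
    out
  })
  for (cid in c("LOW", "HIGH")) {
    truth <- median(p$ground_truth$true_ncr[
      p$ground_truth$condition_id == cid & p$ground_truth$transfected])
    est <- suppressWarnings(
      condition_ncr(wells[wells$condition_id == cid, ], min_wells = 2))
    expect_lt(abs(est$mean_ncr - truth) / truth, 0.10)
  }
})
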