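test_that("enhancement removes flat background and preserves object amplitude", {
  flat <- matrix(500, 128, 128)
  expect_true(all(enhance(flat) == 0))

  # disk of amplitude A over constant background B
  img <- matrix(200, 128, 128)
  rows <- matrix(rep(seq_len(128), 128), 128)
  cols <- t(rows)
  disk <- (rows - 64)^2 + (cols - 64)^2 <= 8^2
  img[disk] <- img[disk] + 900
  out <- enhance(img)
  expect_true(all(out >= 0))
  expect_lt(abs(mean(out[disk]) - 900) / 900, 0.05)
  expect_lt(mean(out[!disk]), 5)
})

test_that("mixture-model foreground detection isolates planted bright disks", {
  set.seed(21)
  img <- matrix(rnorm(256 * 256, 100, 5), 256, 256)
  rows <- matrix(rep(seq_len(256), 256), 256)
  cols <- t(rows)
  truth <- matrix(FALSE, 256, 256)
  for (ctr in list(c(60, 60), c(60, 180), c(180, 60), c(180, 180), c(120, 120))) {
    d <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= 14^2
    img[d] <- rnorm(sum(d), 1000, 50)
    truth <- truth | d
  }
  mask <- detect_foreground_gmm(img, n_components = 2, seed = 1)
  expect_gte(mean(mask[truth]), 0.95)   # covers the disks
  expect_lte(mean(mask[!truth]), 0.01)  # nearly no background
  expect_lt(abs(mean(mask) - mean(truth)) / mean(truth), 0.10)

  # determinism given the seed
  expect_identical(mask, detect_foreground_gmm(img, n_components = 2, seed = 1))
})

test_that("degenerate constant input yields an all-background mask with a warning", {
  expect_warning(mask <- detect_foreground_gmm(matrix(7, 64, 64)), "degenerate")
  expect_false(any(mask))
})

test_that("seeded watershed separates touching cells and finds isolated ones", {
  # two overlapping disks, two separated nuclei
  cfg <- sim_config(image_size = c(128L, 128L), background_level = 100,
                    noise_sd = 0, blur_sigma = 1, transfection_fraction = 1)
  canvas <- list(nuclear = matrix(0, 128, 128), reporter = matrix(0, 128, 128))
  mk <- function(r, c) list(center_row = r, center_col = c, cell_radius = 12,
                            nucleus_radius = 6, true_ncr = 2, transfected = TRUE)
  canvas <- render_cell(canvas, mk(64, 56), cfg)
  canvas <- render_cell(canvas, mk(64, 74), cfg) # centres 18 px apart: overlap
  nuclear <- canvas$nuclear + 100
  reporter <- canvas$reporter + 100
  mask <- nuclear + reporter > 250
  maps <- segment_cells(enhance(nuclear), enhance(reporter), mask)
  expect_equal(max(maps$cell_labels), 2)
  # each nucleus sits inside its own cell
  expect_true(all(maps$cell_labels[maps$nucleus_labels == 1] == 1))
  expect_true(all(maps$cell_labels[maps$nucleus_labels == 2] == 2))

  # blank input: no seeds, zero cells
  blank <- segment_cells(matrix(0, 64, 64), matrix(0, 64, 64),
                         matrix(FALSE, 64, 64))
  expect_equal(max(blank$cell_labels), 0)
})

test_that("well-separated simulated cells are each recovered once", {
  cfg <- sim_config(image_size = c(512L, 512L), cells_per_well = 50,
                    conditions = list(V = c(median = 2, dispersion = 0.1)),
                    wells_per_condition = 1, min_separation = 40, seed = 9)
  p <- generate_plate(cfg)
  seg <- segment_well(p$wells[[1]])
  expect_equal(max(seg$maps$cell_labels), 50)
})

test_that("label maps satisfy containment and consecutive labelling", {
  cfg <- test_sim_config(cells_per_well = 40)
  p <- generate_plate(cfg)
  seg <- segment_well(p$wells[[1]])
  cl <- seg$maps$cell_labels
  nl <- seg$maps$nucleus_labels
  n <- max(cl)
  expect_setequal(unique(cl[cl > 0]), seq_len(n))
  expect_setequal(unique(nl[nl > 0]), seq_len(n))
  # nucleus pixels of label k lie inside cell k
  expect_true(all(cl[nl > 0] == nl[nl > 0]))
})

test_that("morphological refinement drops rule violations and debris", {
  # direct rule: undersized object removed, conforming object kept
  cl <- matrix(0L, 40, 40)
  nl <- matrix(0L, 40, 40)
  cl[5:16, 5:16] <- 1L; nl[8:13, 8:13] <- 1L     # 144 px cell, 36 px nucleus
  cl[30:32, 30:32] <- 2L; nl[31, 31] <- 2L       # 9 px speck
  maps <- structure(list(cell_labels = cl, nucleus_labels = nl),
                    class = "label_maps")
  ref <- refine(maps, morphology_rules(min_cell_area = 40, min_nucleus_area = 10))
  expect_equal(max(ref$cell_labels), 1)
  expect_equal(sum(ref$cell_labels == 1), 144)

  # no-op case: all objects within bounds -> identical up to relabelling
  ref2 <- refine(structure(list(cell_labels = cl * (cl == 1L),
                                nucleus_labels = nl * (nl == 1L)),
                           class = "label_maps"),
                 morphology_rules(min_cell_area = 40, min_nucleus_area = 10))
  expect_equal(sum(ref2$cell_labels > 0), 144)

  # simulated plate with planted debris: only true cells survive
  cfg <- test_sim_config(cells_per_well = 30, n_debris = 15,
                         wells_per_condition = 1)
  p <- generate_plate(cfg)
  seg <- segment_well(p$wells[[1]])
  n_detected <- max(seg$maps$cell_labels)
  expect_lte(abs(n_detected - 30), 2)
})

test_that("the end-to-end chain recovers counts and centroids on a default-noise plate", {
  cfg <- test_sim_config(cells_per_well = 60, wells_per_condition = 1,
                         conditions = list(V = c(median = 2, dispersion = 0.1)))
  p <- generate_plate(cfg)
  seg <- segment_well(p$wells[[1]])
  gt <- p$ground_truth
  n <- max(seg$maps$cell_labels)
  expect_lte(abs(n - nrow(gt)) / nrow(gt), 0.05)
  feats <- label_features(seg$maps)
  d <- outer(feats$centroid_row, gt$center_row, "-")^2 +
    outer(feats$centroid_col, gt$center_col, "-")^2
  nearest <- sqrt(apply(d, 1, min))
  expect_gte(mean(nearest <= mean(gt$cell_radius)), 0.95)
})
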