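test_that("activity scores are anchored at WT = 0% and known mutation = 100%", {
  expect_equal(normalize_score(1.0, 1.0, 3.0), 0)
  expect_equal(normalize_score(3.0, 1.0, 3.0), 100)
  expect_equal(normalize_score(2.0, 1.0, 3.0), 50)
  # not clamped
  expect_lt(normalize_score(0.5, 1.0, 3.0), 0)
  expect_gt(normalize_score(3.5, 1.0, 3.0), 100)
  expect_error(normalize_score(2, 1.5, 1.5), "undefined")
})

test_that("activity scores are invariant under positive affine maps of the NCRs", {
  set.seed(101)
  for (i in seq_len(1000)) {
    wt <- runif(1, 0.5, 2)
    mt <- wt + runif(1, 0.1, 3)
    vus <- runif(1, 0.3, 4)
    a <- runif(1, 0.1, 5)
    b <- runif(1, -1, 1)
    expect_equal(normalize_score(a * vus + b, a * wt + b, a * mt + b),
                 normalize_score(vus, wt, mt), tolerance = 1e-9)
  }
  # monotone in the tested NCR when mt > wt
  s <- normalize_score(seq(0.5, 3, by = 0.25), 1, 3)
  expect_true(all(diff(s) > 0))
})

test_that("the t-test against wild-type behaves at its edges and matches a permutation oracle", {
  expect_equal(ttest_vs_wt(rep(2, 6), rep(2, 6)), 1)
  expect_lt(ttest_vs_wt(c(5, 5.1, 4.9, 5, 5.05, 4.95), rep(1, 6)), 0.001)
  expect_error(ttest_vs_wt(c(1, 2), rep(1, 6)), "at least 3")

  # accept/reject agreement with a permutation oracle at alpha = 0.05
  set.seed(77)
  agree <- logical(100)
  for (i in seq_len(100)) {
    shift <- sample(c(0, 0.5, 1.5), 1)
    a <- rnorm(6, 1, 0.3)
    b <- rnorm(6, 1 + shift, 0.3)
    p_t <- ttest_vs_wt(b, a)
    p_perm <- permutation_p(b, a, n_perm = 2000)
    agree[i] <- (p_t < 0.05) == (p_perm < 0.05)
  }
  # binomial tolerance: the two tests may disagree near the threshold
  expect_gte(mean(agree), 0.90)
})

test_that("the 20% activity cutoff is inclusive and matches the cohort's calls", {
  expect_true(call_activity(20.0))
  expect_false(call_activity(19.9))
  expect_true(call_activity(100))

  cohort <- load_cohort()
  met <- cohort[cohort$gene == "MET" & cohort$protein_change == "R988C", ]
  kit <- cohort[cohort$gene == "KIT" & cohort$protein_change == "V852I", ]
  expect_true(met$active)
  expect_false(kit$active)
})

test_that("dose series span the printed endpoints with constant log spacing", {
  s <- build_dose_series("sorafenib")
  expect_length(s, 6)
  expect_equal(s[1], 1)
  expect_equal(s[6], 1500)
  ratios <- s[-1] / s[-6]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-9)

  im <- build_dose_series("imatinib")
  expect_equal(range(im), c(2.5, 2500))
  expect_length(build_dose_series("vemurafenib"), 6)
  expect_equal(range(build_dose_series("lapatinib")), c(2.5, 2500))
  expect_error(build_dose_series("aspirin"), "sorafenib")
})

test_that("inhibition calls use the activation cutoff and are monotone", {
  expect_true(call_inhibition(c(90, 70, 40, 15, 5, 2), 95))
  expect_false(call_inhibition(c(90, 85, 80, 75, 70, 65), 95))
  expect_false(call_inhibition(rep(20, 6), 95)) # strictly below
  expect_error(call_inhibition(c(10, 5, 2, 1, 1, 1), 15), "not active")

  # monotone: lowering any dose activity never flips inhibited -> not
  set.seed(13)
  for (i in seq_len(50)) {
    act <- runif(6, 0, 100)
    base <- call_inhibition(act, 90)
    lower <- act - runif(6, 0, 30)
    if (base) expect_true(call_inhibition(lower, 90))
  }

  # relative mode: below 20% of the untreated activity
  expect_false(call_inhibition(c(90, 70, 40, 25, 22, 21), 100, mode = "relative"))
  expect_true(call_inhibition(c(90, 70, 40, 25, 22, 19), 100, mode = "relative"))
})

test_that("the packaged dose-response encodings reproduce the assay outcomes", {
  dr <- dose_response_fixture()
  calls <- dr |>
    dplyr::group_by(patient_id, variant_combo, drug) |>
    dplyr::arrange(dose_nM, .by_group = TRUE) |>
    dplyr::summarise(inhibited = call_inhibition(activity, untreated_activity[1]),
                     .groups = "drop")
  expect_true(calls$inhibited[calls$variant_combo == "FLT3 M665T"])
  expect_true(calls$inhibited[calls$variant_combo == "KIT D572G"])
  expect_true(calls$inhibited[calls$variant_combo == "BRAF V600E"])
  expect_false(calls$inhibited[calls$variant_combo == "ERBB2 T862A + KRAS G12S"])
  # six strictly increasing doses inside the drug's printed range
  spans <- dr |>
    dplyr::group_by(variant_combo, drug) |>
    dplyr::summarise(n = dplyr::n(), increasing = all(diff(dose_nM) > 0),
                     lo = min(dose_nM), hi = max(dose_nM), .groups = "drop")
  expect_true(all(spans$n == 6))
  expect_true(all(spans$increasing))
  for (i in seq_len(nrow(spans))) {
    rng <- range(build_dose_series(spans$drug[i]))
    expect_gte(spans$lo[i], rng[1] * (1 - 1e-9))
    expect_lte(spans$hi[i], rng[2] * (1 + 1e-9))
  }
})

test_that("condition tables are scored against their anchors", {
  conds <- tibble::tibble(
    condition_id = c("WT", "MT", "V1", "V2"),
    mean_ncr = c(1, 3, 2, 1.1),
    well_medians = list(c(0.95, 1, 1.05, 1, 0.98, 1.02),
                        c(2.9, 3, 3.1, 3, 2.95, 3.05),
                        c(1.9, 2, 2.1, 2, 1.95, 2.05),
                        c(1.05, 1.1, 1.15, 1.1, 1.08, 1.12))
  )
  sc <- score_activity(conds)
  expect_equal(sc$score[sc$condition_id == "V1"], 50)
  expect_equal(sc$score[sc$condition_id == "V2"], 5)
  expect_true(sc$active[sc$condition_id == "V1"])
  expect_false(sc$active[sc$condition_id == "V2"])
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
})
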