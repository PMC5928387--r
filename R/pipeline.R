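#' Pipeline run configuration
#'
#' Collects the per-stage parameter blocks for [run_pipeline()] and
#' [run_stage()] and validates all of them up front, before any stage runs.
#'
#' @param simulation a [sim_config()]. Its `conditions` should include the
#'   anchors named by the scoring block.
#' @param segmentation list: `n_components`, `subsample`, `min_seed_distance`,
#'   `seed_smooth_sigma`, `topo_sigma`, `lambda`, `enhance_radius`, `rules`
#'   (a [morphology_rules()]).
#' @param quantification list: `epsilon`, `min_cells_per_well`, `gate_k`.
#' @param scoring list: `cutoff`, `inhibition_mode`, `var_equal`, `wt`, `mt`
#'   (anchor condition ids).
#' @param prediction list of optional fixture paths: `cohort`, `responses`,
#'   `literature`, `targets` (`NULL` = packaged fixtures).
#' @param outdir optional output directory; when set, every stage writes its
#'   CSV/JSON outputs there.
#' @param seed global seed; overrides `simulation$seed` and seeds the GMM
#'   subsampling, so one integer determines every stochastic choice.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = sim_config(
                         conditions = list(WT = c(median = 1, dispersion = 0.1),
                                           MT = c(median = 3, dispersion = 0.1),
                                           VUS = c(median = 2, dispersion = 0.1))),
                       segmentation = list(),
                       quantification = list(),
                       scoring = list(),
                       prediction = list(),
                       outdir = NULL,
                       seed = 1L) {
  seg <- utils::modifyList(list(n_components = 3, subsample = 20000,
                                min_seed_distance = 7, seed_smooth_sigma = 2,
                                topo_sigma = 2, lambda = 1e-4,
                                enhance_radius = 25,
                                rules = morphology_rules()), segmentation)
  qnt <- utils::modifyList(list(epsilon = 1, min_cells_per_well = 50,
                                gate_k = 3), quantification)
  sco <- utils::modifyList(list(cutoff = 20, inhibition_mode = "absolute",
                                var_equal = FALSE, wt = "WT", mt = "MT"),
                           scoring)
  prd <- utils::modifyList(list(cohort = NULL, responses = NULL,
                                literature = NULL, targets = NULL), prediction)
  simulation$seed <- as.integer(seed)
  validate_sim_config(simulation)
  if (!inherits(seg$rules, "morphology_rules"))
    abort("segmentation$rules must come from morphology_rules()",
          class = "ncrscreen_config_error")
  if (qnt$min_cells_per_well < 1 || qnt$epsilon < 0)
    abort("invalid quantification block", class = "ncrscreen_config_error")
  if (!sco$inhibition_mode %in% c("absolute", "relative"))
    abort("scoring$inhibition_mode must be 'absolute' or 'relative'",
          class = "ncrscreen_config_error")
  for (p in purrr::compact(prd)) if (!file.exists(p))
    abort(paste0("fixture path does not exist: ", p),
          class = "ncrscreen_config_error")
  structure(list(simulation = simulation, segmentation = seg,
                 quantification = qnt, scoring = sco, prediction = prd,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

stage_names <- c("simulate", "segment", "quantify", "score", "predict", "stats")

#' Run one pipeline stage
#'
#' Runs a single stage on explicit inputs, producing exactly the result the
#' same stage produces inside [run_pipeline()].
#'
#' @param name one of `"simulate"`, `"segment"`, `"quantify"`, `"score"`,
#'   `"predict"`, `"stats"`.
#' @param config a [run_config()].
#' @param inputs named list of upstream results: `plate` (for segment),
#'   `plate` + `maps` (quantify), `conditions` (score), none (predict, which
#'   reads its fixtures), `cohort` + `predictions` (stats).
#' @return the stage result (see [run_pipeline()]).
#' @export
run_stage <- function(name, config, inputs = list()) {
  if (!name %in% stage_names)
    abort(paste0("unknown stage '", name, "'; stages: ",
                 paste(stage_names, collapse = ", ")))
  seg <- config$segmentation
  qnt <- config$quantification
  sco <- config$scoring
  prd <- config$prediction
  switch(name,
    simulate = generate_plate(config$simulation),
    segment = {
      plate <- inputs$plate %||% abort("segment stage needs inputs$plate")
      purrr::map(plate$wells, function(w) {
        nuc <- enhance(w$nuclear, radius = seg$enhance_radius)
        rep_ <- enhance(w$reporter, radius = seg$enhance_radius)
        # foreground detection uses the raw channels: their background is a
        # clean Gaussian, whereas subtraction clamps it to a point mass at 0
        mask <- detect_foreground_gmm(list(w$nuclear, w$reporter),
                                      n_components = seg$n_components,
                                      subsample = seg$subsample,
                                      seed = config$seed)
        maps <- segment_cells(nuc, rep_, mask,
                              min_seed_distance = seg$min_seed_distance,
                              seed_smooth_sigma = seg$seed_smooth_sigma,
                              topo_sigma = seg$topo_sigma, lambda = seg$lambda)
        maps <- refine(maps, seg$rules)
        list(maps = maps, reporter = rep_, well_id = w$well_id,
             condition_id = w$condition_id)
      })
    },
    quantify = {
      maps <- inputs$maps %||% abort("quantify stage needs inputs$maps")
      wells <- purrr::map_dfr(maps, function(m) {
        cells <- quantify_cells(m$maps, m$reporter, well_id = m$well_id,
                                epsilon = qnt$epsilon, gate_k = qnt$gate_k)
        w <- suppressWarnings(well_ncr(cells, min_cells = qnt$min_cells_per_well))
        w$well_id <- m$well_id
        w$condition_id <- m$condition_id
        w
      })
      if (!any(wells$valid))
        abort(paste0("too few cells: no valid wells; wells flagged invalid: ",
                     paste(wells$well_id, collapse = ", ")))
      conditions <- wells %>%
        dplyr::group_by(.data$condition_id) %>%
        dplyr::group_split() %>%
        purrr::map_dfr(condition_ncr)
      list(wells = wells, conditions = conditions)
    },
    score = {
      conditions <- inputs$conditions %||% abort("score stage needs inputs$conditions")
      activity <- score_activity(conditions, wt = sco$wt, mt = sco$mt,
                                 cutoff = sco$cutoff, var_equal = sco$var_equal)
      responses <- dose_response_fixture(prd$responses) %>%
        dplyr::group_by(.data$patient_id, .data$variant_combo, .data$drug) %>%
        dplyr::arrange(.data$dose_nM, .by_group = TRUE) %>%
        dplyr::summarise(
          untreated_activity = .data$untreated_activity[1],
          inhibited = call_inhibition(.data$activity, .data$untreated_activity[1],
                                      mode = sco$inhibition_mode,
                                      cutoff = sco$cutoff),
          .groups = "drop")
      list(activity = activity, responses = responses)
    },
    predict = {
      cohort <- load_cohort(prd$cohort %||% "builtin")
      predictions <- predict_cohort(
        cohort,
        responses = dose_response_fixture(prd$responses),
        literature = literature_rules(prd$literature),
        targets = drug_targets(prd$targets),
        inhibition_mode = sco$inhibition_mode)
      list(cohort = cohort, predictions = predictions)
    },
    stats = {
      cohort <- inputs$cohort %||% abort("stats stage needs inputs$cohort")
      predictions <- inputs$predictions %||% abort("stats stage needs inputs$predictions")
      survival_by_prediction(cohort, predictions)
    }
  )
}

#' Run the full pipeline
#'
#' Executes simulate, segment, quantify, score, predict and stats in order.
#' Any stage failure aborts with the stage named. With `config$outdir` set,
#' the per-stage CSV/JSON outputs are written there. Re-running with an
#' identical config and seed reproduces identical numeric outputs.
#'
#' @param config a [run_config()].
#' @return list of class `ncr_run`: `plate`, `segmented`, `wells`,
#'   `conditions`, `activity`, `responses`, `cohort`, `predictions`, `stats`,
#'   and `manifest` (config hash, stage timings and object counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  results <- list()
  timings <- numeric(0)
  run1 <- function(name, inputs = list()) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(run_stage(name, config, inputs),
                    error = function(e) abort(
                      paste0("stage '", name, "' failed: ", conditionMessage(e)),
                      parent = e))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  results$plate <- run1("simulate")
  results$segmented <- run1("segment", list(plate = results$plate))
  q <- run1("quantify", list(maps = results$segmented))
  results$wells <- q$wells
  results$conditions <- q$conditions
  s <- run1("score", list(conditions = results$conditions))
  results$activity <- s$activity
  results$responses <- s$responses
  p <- run1("predict")
  results$cohort <- p$cohort
  results$predictions <- p$predictions
  results$stats <- run1("stats", list(cohort = results$cohort,
                                      predictions = results$predictions))
  results$manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    timings = timings,
    counts = list(wells = nrow(results$wells),
                  valid_wells = sum(results$wells$valid),
                  conditions = nrow(results$conditions),
                  active_variants = sum(results$activity$active),
                  positive_predictions = sum(results$predictions$label == "positive"))
  )
  if (!is.null(config$outdir)) write_run_outputs(results, config$outdir)
  structure(results, class = "ncr_run")
}

write_run_outputs <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(results$wells, file.path(outdir, "wells.csv"))
  readr::write_csv(dplyr::select(results$conditions, -"well_medians"),
                   file.path(outdir, "conditions.csv"))
  readr::write_csv(results$activity, file.path(outdir, "activity.csv"))
  readr::write_csv(results$responses, file.path(outdir, "dose_response.csv"))
  readr::write_csv(results$predictions, file.path(outdir, "predictions.csv"))
  write_survival_json(results$stats, file.path(outdir, "stats.json"))
  rlang::check_installed("jsonlite")
  jsonlite::write_json(results$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
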