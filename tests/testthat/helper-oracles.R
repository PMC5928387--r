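# Independent oracles used to cross-check the package implementations.

# Kruskal-Wallis H by explicit sorting and mid-rank assignment, with the
# tie correction 1 - sum(t^3 - t) / (N^3 - N).
brute_force_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  ord <- order(x)
  r <- numeric(N)
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j) # mid-rank over the tie run
    i <- j + 1
  }
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(v) sum(v)^2 / length(v))) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / corr
}

# Product-limit estimator computed step by step from the risk-set table.
hand_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- as.logical(events)[ord]
  ut <- unique(times)
  surv <- numeric(0); out_t <- numeric(0)
  s <- 1
  for (t in ut) {
    at_risk <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / at_risk)
    out_t <- c(out_t, t); surv <- c(surv, s)
  }
  list(time = out_t, survival = surv)
}

# Two-sided permutation test of a mean difference (complete-ish Monte Carlo).
permutation_p <- function(a, b, n_perm = 2000) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  n <- length(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), n)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# Small simulator configuration shared across imaging tests.
test_sim_config <- function(...) {
  args <- utils::modifyList(
    list(image_size = c(256L, 256L), cells_per_well = 60,
         wells_per_condition = 2, seed = 11),
    list(...))
  do.call(sim_config, args)
}

# Run enhancement + detection + segmentation + refinement on one well.
segment_well <- function(well, seed = 1, rules = morphology_rules()) {
  nuc <- enhance(well$nuclear)
  rep_ <- enhance(well$reporter)
  mask <- detect_foreground_gmm(list(well$nuclear, well$reporter),
                                n_components = 3, seed = seed)
  list(maps = refine(segment_cells(nuc, rep_, mask), rules),
       nuclear = nuc, reporter = rep_)
}
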