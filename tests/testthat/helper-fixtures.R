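# Shared fixture builders. All fixtures are generated in code.

# A long-format vitals table from (channel -> list of (time, value)) pairs
# for a single subject.
make_vitals <- function(obs, subject_id = 1L) {
  do.call(rbind, lapply(names(obs), function(ch) {
    m <- obs[[ch]]
    data.frame(subject_id = subject_id, time_hr = m[, 1], channel = ch,
               value = m[, 2], stringsAsFactors = FALSE)
  }))
}

# A single-subject hourly grid with the given per-channel 12-vectors
# (unspecified channels fully observed at a constant).
make_grid <- function(..., fill = 100) {
  given <- list(...)
  rows <- lapply(trajtargets:::VITAL_CHANNELS, function(ch)
    if (!is.null(given[[ch]])) given[[ch]] else rep(fill, 12))
  m <- matrix(unlist(rows), nrow = 1)
  colnames(m) <- paste(rep(trajtargets:::VITAL_CHANNELS, each = 12),
                       0:11, sep = ".")
  rownames(m) <- "1"
  structure(m, horizon = 12L, class = c("hourly_grids", "matrix"))
}

# Random row-stochastic posterior matrix.
random_posterior <- function(n, K) {
  W <- matrix(stats::rexp(n * K), n, K)
  W / rowSums(W)
}

# Random complete grids drawn from a random mixture of polynomial
# trajectories (for EM property tests).
random_mixture_grids <- function(n = 60, K = 2, V = 2, horizon = 12,
                                 seed = 1) {
  set.seed(seed)
  tc <- (0:(horizon - 1)) - (horizon - 1) / 2
  g <- sample.int(K, n, replace = TRUE)
  Y <- matrix(NA_real_, n, V * horizon)
  for (gg in seq_len(K)) for (v in seq_len(V)) {
    b <- stats::rnorm(3, 0, c(2, 0.4, 0.05))
    mu <- b[1] + b[2] * tc + b[3] * tc^2
    i <- g == gg
    Y[i, (v - 1) * horizon + seq_len(horizon)] <-
      matrix(mu, sum(i), horizon, byrow = TRUE) +
      stats::rnorm(sum(i) * horizon, 0, stats::runif(1, 0.3, 1))
  }
  structure(Y, horizon = as.integer(horizon),
            class = c("hourly_grids", "matrix"), group = g)
}

# A cohort with true cluster labels attached (outcomes only).
labeled_cohort <- function(n = 2000, seed = 1, config = default_scenario()) {
  config$n_subjects <- as.integer(n)
  config$seed <- as.integer(seed)
  sim <- simulate_cohort(config, vitals = FALSE)
  d <- sim$cohort
  d$cluster <- sim$truth$group
  list(data = d, truth = sim$truth, config = config)
}
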