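## Synthetic cohort generator: seeded cohorts with the latent structure the
## downstream analysis assumes (trajectory groups, group-dependent hazards,
## U-shaped blood gas risk), plus controlled missingness and outlier injection.

#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic generator: latent group structure,
#' per-group polynomial vital-sign trajectories, survival mechanism, blood gas
#' risk geometry, and corruption rates. `default_scenario()` returns a fully
#' populated 3-group configuration.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param mixing Probability vector over the K latent groups (sums to 1).
#' @param traj_coeffs Numeric array `K x 6 x 4`: per (group, channel)
#'   polynomial coefficients (intercept, linear, quadratic, cubic) in native
#'   channel units, on time centered at the 12-hour window midpoint (5.5 h).
#'   Channel order: HR, RR, SBP, DBP, MAP, SpO2.
#' @param noise_sd `K x 6` matrix of residual SDs per (group, channel).
#' @param obs_per_hour Integer vector of admissible raw observation counts per
#'   subject-channel-hour; each cell draws its count uniformly from this set.
#' @param missing_rate Per-cell independent deletion probability used by
#'   [inject_missingness()].
#' @param long_gap_rate Probability a subject receives one contiguous run of
#'   >= 5 missing hours on one channel.
#' @param outlier_rate Per-observation probability of replacement by a
#'   physiologically implausible value ([inject_outliers()]).
#' @param plausibility Plausibility ranges, as from [default_plausibility()].
#' @param hazard_shape,hazard_scale Weibull baseline survival parameters
#'   (shape, scale in days) for the latent death time.
#' @param group_loghr Per-group log hazard multiplier on the Weibull hazard
#'   (and on the ICU-death logit); the reference group carries 0.
#' @param covar_loghr Named vector: log-hazard per year of age (centered at
#'   65) and per SOFA point (centered at 6) entering the latent hazard.
#'   Defaults to zero so that the configured group hazard ratio is the exact
#'   marginal estimand at every covariate-adjustment level.
#' @param icu_intercept Intercept of the ICU-death logistic model (logit of
#'   the reference-group ICU mortality at centered covariates, all gas values
#'   inside their low-risk intervals).
#' @param icu_covar Named vector: age and SOFA coefficients of the ICU-death
#'   logit.
#' @param gas_params Data frame with one row per blood gas parameter and
#'   columns `param`, `mean`, `sd`, `a`, `b`, `slope`: values are drawn from a
#'   truncated normal `(mean, sd)`; the excess-risk term on the ICU-death logit
#'   is 0 inside `[a, b]` and `slope` per SD of distance outside it.
#' @param censor_rate Fraction of subjects receiving uniform random early
#'   censoring on `[0, 365]` days (others are censored administratively at the
#'   horizon).
#' @param seed Integer seed; identical configurations produce byte-identical
#'   cohorts.
#' @return An object of class `traj_config` (a validated list).
#' @seealso [default_scenario()], [simulate_cohort()]
#' @export
traj_config <- function(n_subjects = 600,
                        mixing = c(0.24, 0.35, 0.41),
                        traj_coeffs = default_traj_coeffs(),
                        noise_sd = default_noise_sd(nrow(traj_coeffs)),
                        obs_per_hour = 2:4,
                        missing_rate = 0.03,
                        long_gap_rate = 0.02,
                        outlier_rate = 0.005,
                        plausibility = default_plausibility(),
                        hazard_shape = 1.1,
                        hazard_scale = 700,
                        group_loghr = c(0, log(1.5), 0),
                        covar_loghr = c(age = 0, sofa = 0),
                        icu_intercept = -2.1,
                        icu_covar = c(age = 0.02, sofa = 0.08),
                        gas_params = default_gas_params(),
                        censor_rate = 0.10,
                        seed = 1L) {
  cfg <- list(n_subjects = n_subjects, mixing = mixing,
              traj_coeffs = traj_coeffs, noise_sd = noise_sd,
              obs_per_hour = as.integer(obs_per_hour),
              missing_rate = missing_rate, long_gap_rate = long_gap_rate,
              outlier_rate = outlier_rate, plausibility = plausibility,
              hazard_shape = hazard_shape, hazard_scale = hazard_scale,
              group_loghr = group_loghr, covar_loghr = covar_loghr,
              icu_intercept = icu_intercept, icu_covar = icu_covar,
              gas_params = gas_params, censor_rate = censor_rate,
              seed = as.integer(seed))
  class(cfg) <- "traj_config"
  validate_traj_config(cfg)
  cfg
}

validate_traj_config <- function(cfg) {
  K <- length(cfg$mixing)
  if (abs(sum(cfg$mixing) - 1) > 1e-12)
    stop_input("`mixing` must sum to 1 (got ", format(sum(cfg$mixing), digits = 16), ")")
  if (any(cfg$mixing < 0)) stop_input("`mixing` must be non-negative")
  if (!is.array(cfg$traj_coeffs) || length(dim(cfg$traj_coeffs)) != 3L ||
      dim(cfg$traj_coeffs)[1] != K)
    stop_input("`traj_coeffs` must be a K x 6 x 4 array with K = length(mixing)")
  if (dim(cfg$traj_coeffs)[2] != length(VITAL_CHANNELS) || dim(cfg$traj_coeffs)[3] != 4L)
    stop_input("`traj_coeffs` must have 6 channels and 4 polynomial coefficients")
  if (!all(dim(cfg$noise_sd) == c(K, length(VITAL_CHANNELS))))
    stop_input("`noise_sd` must be a K x 6 matrix")
  if (any(cfg$noise_sd <= 0)) stop_input("all residual SDs must be > 0")
  for (r in c("missing_rate", "long_gap_rate", "outlier_rate", "censor_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop_input("`", r, "` must lie in [0, 1]")
  if (length(cfg$group_loghr) != K)
    stop_input("`group_loghr` must have one entry per group")
  gp <- cfg$gas_params
  need <- c("param", "mean", "sd", "a", "b", "slope")
  if (!all(need %in% names(gp))) stop_input("`gas_params` missing columns")
  if (any(gp$a >= gp$b)) stop_input("every gas interval must satisfy a < b")
  if (any(gp$sd <= 0)) stop_input("gas SDs must be > 0")
  if (cfg$n_subjects < K) stop_input("`n_subjects` must be >= number of groups")
  invisible(cfg)
}

#' @rdname traj_config
#' @details `default_scenario()` is the canonical study condition: three
#'   latent groups mixed 24/35/41 percent whose mean trajectories reproduce the
#'   qualitative cluster signatures seen in early-ICU vital-sign phenotyping —
#'   group 1 hypertensive (elevated SBP/DBP/MAP), group 2 hyperdynamic and
#'   hypoxic (elevated HR/RR, reduced SpO2) with a 1.5-fold hazard, group 3
#'   hypotensive with high SpO2 (the low-risk reference). Every pair of groups
#'   is separated by at least 2 residual SDs in at least one channel at the
#'   window midpoint.
#' @export
default_scenario <- function(n_subjects = 600, seed = 1L) {
  traj_config(n_subjects = n_subjects, seed = seed)
}

#' @rdname traj_config
#' @export
default_traj_coeffs <- function() {
  K <- 3L; V <- length(VITAL_CHANNELS)
  a <- array(0, dim = c(K, V, 4L),
             dimnames = list(NULL, VITAL_CHANNELS,
                             c("intercept", "linear", "quadratic", "cubic")))
  # time centered at 5.5 h; units native to each channel
  a[1, "HR", 1:2]   <- c(88, -0.3)
  a[1, "RR", 1]     <- 18
  a[1, "SBP", 1:3]  <- c(165, 1.0, -0.10)
  a[1, "DBP", 1:2]  <- c(95, 0.3)
  a[1, "MAP", 1:3]  <- c(118, 0.5, -0.05)
  a[1, "SpO2", 1]   <- 96
  a[2, "HR", 1:2]   <- c(118, 0.5)
  a[2, "RR", 1:2]   <- c(30, 0.3)
  a[2, "SBP", 1]    <- 115
  a[2, "DBP", 1]    <- 65
  a[2, "MAP", 1]    <- 82
  a[2, "SpO2", 1:2] <- c(89, -0.2)
  a[3, "HR", 1]     <- 78
  a[3, "RR", 1]     <- 16
  a[3, "SBP", 1:2]  <- c(95, -0.5)
  a[3, "DBP", 1]    <- 52
  a[3, "MAP", 1:2]  <- c(66, -0.3)
  a[3, "SpO2", 1]   <- 98
  a
}

#' @rdname traj_config
#' @export
default_noise_sd <- function(K = 3L) {
  matrix(rep(c(HR = 6, RR = 2.5, SBP = 8, DBP = 6, MAP = 6, SpO2 = 1.5),
             each = K),
         nrow = K, dimnames = list(NULL, VITAL_CHANNELS))
}

#' @rdname traj_config
#' @details Default gas intervals are `mean +/- 1.2 SD`; the excess-risk slope
#'   is expressed per SD of distance beyond the interval, on the logit scale.
#' @export
default_gas_params <- function() {
  gp <- data.frame(
    param = GAS_PARAMS,
    mean  = c(7.38, 95, 40, 2.5, -1, 24),
    sd    = c(0.08, 30, 9, 1.5, 4, 5),
    slope = c(0.9, 0.7, 0.8, 0.8, 0.8, 0.8),
    units = c("", "mmHg", "mmHg", "mmol/L", "mEq/L", "mEq/L"),
    stringsAsFactors = FALSE)
  gp$a <- gp$mean - 1.2 * gp$sd
  gp$b <- gp$mean + 1.2 * gp$sd
  gp[, c("param", "mean", "sd", "a", "b", "slope", "units")]
}

# Evaluate the group-mean trajectory of channel `v` for group `g` at times `t`
# (hours since admission).
traj_mean <- function(cfg, g, v, t) {
  tc <- t - 5.5
  b <- cfg$traj_coeffs[g, v, ]
  b[1] + b[2] * tc + b[3] * tc^2 + b[4] * tc^3
}

#' Generate a synthetic ICU cohort with known latent structure
#'
#' Draws latent trajectory-group labels, covariates, blood gas values, survival
#' outcomes, and (optionally) raw multi-channel vital-sign observations at
#' jittered within-hour timestamps.
#'
#' The survival mechanism couples a latent Weibull death time with the ICU
#' stay through a shared uniform draw per subject. The latent death time
#' follows a Weibull proportional-hazards model in the group effect (plus
#' mild age and SOFA effects); 28/90/365-day outcomes derive from it alone,
#' so the configured group hazard ratio is exact at those horizons. The ICU
#' stay is a pair of competing exponential risks — death with hazard
#' `lam_dis * exp(lp)` and discharge with hazard `lam_dis` — where
#' `lp = icu_intercept + group effect + covariate terms + gas excess risk`
#' and the gas excess is zero inside each parameter's low-risk interval
#' `[a, b]`, growing linearly with the distance outside it (in SD units).
#' The ICU death probability is therefore exactly `plogis(lp)`, and the
#' cause-specific ICU death hazard is exactly proportional in the gas excess
#' — the structure the spline dose-response and safe-zone stages estimate.
#' Because the latent uniform is shared, ICU deaths coincide with the
#' shortest latent survival times.
#'
#' @param config A [traj_config()].
#' @param vitals If `FALSE`, skip raw vital-sign generation (cohort table and
#'   truth only); used by simulation harnesses that only need outcomes.
#' @return A list of class `synthetic_cohort`:
#' \describe{
#'   \item{vitals}{Long data frame `subject_id`, `time_hr`, `channel`,
#'     `value` (or `NULL` when `vitals = FALSE`).}
#'   \item{cohort}{One row per subject: demographics, covariates, blood gas
#'     values, and per-horizon survival time/event columns.}
#'   \item{truth}{Latent labels, death times, gas low-risk intervals, and a
#'     config echo. Never joined into the analysis inputs.}
#' }
#' @export
simulate_cohort <- function(config, vitals = TRUE) {
  stopifnot(inherits(config, "traj_config"))
  validate_traj_config(config)
  seeds <- derive_seeds(config$seed, 4L)
  set.seed(seeds[1])
  n <- config$n_subjects
  K <- length(config$mixing)

  group <- sample.int(K, n, replace = TRUE, prob = config$mixing)

  age  <- round(pmin(pmax(stats::rnorm(n, 65, 15), 18), 95), 1)
  sex  <- stats::rbinom(n, 1L, 0.55)                       # 1 = male
  race <- sample(c("groupA", "groupB", "groupC"), n, replace = TRUE,
                 prob = c(0.60, 0.25, 0.15))
  sofa <- pmin(pmax(round(stats::rnorm(n, 6, 3)), 0), 24)
  apsiii <- round(pmin(pmax(30 + 4 * sofa + stats::rnorm(n, 0, 10), 0), 200))
  vent <- stats::rbinom(n, 1L, 0.78)
  crrt <- stats::rbinom(n, 1L, 0.18)
  rrt  <- stats::rbinom(n, 1L, 0.21)

  gp <- config$gas_params
  gas <- matrix(NA_real_, n, nrow(gp), dimnames = list(NULL, gp$param))
  excess <- numeric(n)
  for (j in seq_len(nrow(gp))) {
    # contaminated normal: a 3% inflated-SD component gives the heavy tails
    # of real lab values (and populates the far-outside risk stratum)
    heavy <- stats::runif(n) < 0.03
    z <- stats::qnorm(stats::runif(n, stats::pnorm(-4), stats::pnorm(4)))
    z_heavy <- 3 * stats::qnorm(stats::runif(n, stats::pnorm(-2), stats::pnorm(2)))
    x <- gp$mean[j] + gp$sd[j] * ifelse(heavy, z_heavy, z)
    gas[, j] <- x
    d <- pmax(0, (gp$a[j] - x) / gp$sd[j], (x - gp$b[j]) / gp$sd[j])
    excess <- excess + gp$slope[j] * d
  }

  lp_icu <- config$icu_intercept + config$group_loghr[group] +
    config$icu_covar[["age"]] * (age - 65) +
    config$icu_covar[["sofa"]] * (sofa - 6) + excess
  p_icu <- stats::plogis(lp_icu)

  eta <- config$group_loghr[group] +
    config$covar_loghr[["age"]] * (age - 65) +
    config$covar_loghr[["sofa"]] * (sofa - 6)
  u <- stats::runif(n)
  death_time <- config$hazard_scale * (-log1p(-u) / exp(eta))^(1 / config$hazard_shape)

  cens <- ifelse(stats::runif(n) < config$censor_rate,
                 stats::runif(n, 0, 365), Inf)

  # ICU stay as competing exponential risks sharing the latent uniform:
  # death hazard lam_dis * exp(lp_icu), discharge hazard lam_dis. The ICU
  # death probability is then exactly plogis(lp_icu), and the cause-specific
  # death hazard is exactly proportional in the gas excess and covariates.
  lam_dis <- 1 / 7
  t_icu_death <- -log1p(-u) / (lam_dis * exp(lp_icu))
  t_icu_dis <- stats::rexp(n, lam_dis)
  icu_death <- t_icu_death < t_icu_dis
  icu_stay <- pmin(t_icu_death, t_icu_dis)
  icu_death <- icu_death & icu_stay <= 90

  cohort <- data.frame(
    subject_id = seq_len(n), age = age, sex = sex, race = race,
    sofa = sofa, apsiii = apsiii, vent = vent, crrt = crrt, rrt = rrt,
    stringsAsFactors = FALSE)
  for (p in gp$param) cohort[[p]] <- gas[, p]
  cohort$icu_event <- as.integer(icu_death)
  cohort$icu_time  <- pmax(1, ceiling(pmin(icu_stay, 90)))
  for (H in c(28, 90, 365)) {
    ev <- as.integer(death_time <= pmin(cens, H))
    tt <- pmax(1, ceiling(pmin(death_time, cens, H)))
    cohort[[paste0("event_", H)]] <- ev
    cohort[[paste0("time_", H)]]  <- tt
  }

  vt <- NULL
  if (isTRUE(vitals)) {
    set.seed(seeds[2])
    V <- length(VITAL_CHANNELS)
    cells <- expand.grid(hour = 0:11, channel_idx = seq_len(V),
                         subject_id = seq_len(n))
    nobs <- sample(config$obs_per_hour, nrow(cells), replace = TRUE)
    idx <- rep.int(seq_len(nrow(cells)), nobs)
    sub <- cells$subject_id[idx]
    chi <- cells$channel_idx[idx]
    hr  <- cells$hour[idx]
    tm  <- hr + stats::runif(length(idx))
    g   <- group[sub]
    tc  <- tm - 5.5
    co  <- config$traj_coeffs
    mu  <- co[cbind(g, chi, 1L)] + co[cbind(g, chi, 2L)] * tc +
      co[cbind(g, chi, 3L)] * tc^2 + co[cbind(g, chi, 4L)] * tc^3
    val <- mu + stats::rnorm(length(idx), 0, config$noise_sd[cbind(g, chi)])
    # physiological saturation: emitted values stay inside the plausibility
    # range (e.g. SpO2 caps at 100), so injected outliers are the only
    # implausible observations
    pl <- config$plausibility
    pi_ch <- match(VITAL_CHANNELS, pl$channel)
    val <- pmin(pmax(val, pl$lower[pi_ch][chi]), pl$upper[pi_ch][chi])
    vt <- data.frame(subject_id = sub, time_hr = tm,
                     channel = VITAL_CHANNELS[chi], value = val,
                     stringsAsFactors = FALSE)
    vt <- vt[order(vt$subject_id, vt$channel, vt$time_hr), , drop = FALSE]
    rownames(vt) <- NULL
  }

  truth <- list(group = group, death_time = death_time,
                icu_death_prob = p_icu,
                gas_intervals = gp[, c("param", "a", "b")],
                config = config)
  structure(list(vitals = vt, cohort = cohort, truth = truth),
            class = "synthetic_cohort")
}

#' Inject missingness into raw vitals
#'
#' Deletes whole subject-channel-hour cells independently at `missing_rate`,
#' and gives a `long_gap_rate` fraction of subjects one contiguous run of
#' >= 5 missing hours on a single channel (which the preprocessing stage must
#' later exclude). Deletion bookkeeping is returned so downstream exclusions
#' can be verified exactly.
#'
#' @param vitals Long vitals table from [simulate_cohort()].
#' @param config The generating [traj_config()].
#' @return List with elements `vitals` (holed table), `deleted_cells`
#'   (data frame `subject_id`, `channel`, `hour`, `reason`), and
#'   `long_gap_subjects` (data frame `subject_id`, `channel`, `start`, `len`).
#' @export
inject_missingness <- function(vitals, config) {
  stopifnot(inherits(config, "traj_config"))
  if (config$missing_rate < 0 || config$missing_rate > 1 ||
      config$long_gap_rate < 0 || config$long_gap_rate > 1)
    stop_input("missingness rates must lie in [0, 1]")
  seeds <- derive_seeds(config$seed, 4L)
  set.seed(seeds[3])
  subjects <- sort(unique(vitals$subject_id))

  cells <- unique(vitals[, c("subject_id", "channel")])
  cells <- merge(cells, data.frame(hour = 0:11))
  drop_iid <- stats::runif(nrow(cells)) < config$missing_rate
  deleted <- cells[drop_iid, c("subject_id", "channel", "hour")]
  if (nrow(deleted)) deleted$reason <- "iid"

  lg_pick <- subjects[stats::runif(length(subjects)) < config$long_gap_rate]
  lg <- NULL
  if (length(lg_pick)) {
    lg <- data.frame(subject_id = lg_pick,
                     channel = sample(VITAL_CHANNELS, length(lg_pick), TRUE),
                     start = sample(0:7, length(lg_pick), TRUE),
                     len = sample(5:7, length(lg_pick), TRUE))
    gap_cells <- do.call(rbind, lapply(seq_len(nrow(lg)), function(i)
      data.frame(subject_id = lg$subject_id[i], channel = lg$channel[i],
                 hour = lg$start[i] + seq_len(lg$len[i]) - 1L,
                 reason = "long_gap")))
    deleted <- rbind(deleted, gap_cells)
  } else {
    lg <- data.frame(subject_id = integer(), channel = character(),
                     start = integer(), len = integer())
  }

  out <- vitals
  if (nrow(deleted)) {
    key <- function(s, ch, h) paste(s, ch, h, sep = "\r")
    bad <- key(deleted$subject_id, deleted$channel, deleted$hour)
    obs <- key(out$subject_id, out$channel, floor(out$time_hr))
    out <- out[!(obs %in% bad), , drop = FALSE]
    rownames(out) <- NULL
  }
  list(vitals = out, deleted_cells = deleted, long_gap_subjects = lg)
}

#' Inject physiologically implausible outliers
#'
#' Replaces a random `outlier_rate` fraction of observations with values
#' strictly outside the configured plausibility range of their channel, and
#' records the replaced positions so the plausibility filter can be checked
#' against ground truth.
#'
#' @inheritParams inject_missingness
#' @return List with `vitals` (corrupted table) and `outliers` (data frame of
#'   replaced rows: `subject_id`, `time_hr`, `channel`, `original`, `value`).
#' @export
inject_outliers <- function(vitals, config) {
  stopifnot(inherits(config, "traj_config"))
  if (config$outlier_rate < 0 || config$outlier_rate > 1)
    stop_input("`outlier_rate` must lie in [0, 1]")
  seeds <- derive_seeds(config$seed, 4L)
  set.seed(seeds[4])
  pick <- which(stats::runif(nrow(vitals)) < config$outlier_rate)
  out <- vitals
  rec <- data.frame(subject_id = integer(), time_hr = numeric(),
                    channel = character(), original = numeric(),
                    value = numeric())
  if (length(pick)) {
    pl <- config$plausibility
    ch <- out$channel[pick]
    lo <- pl$lower[match(ch, pl$channel)]
    hi <- pl$upper[match(ch, pl$channel)]
    span <- hi - lo
    side_hi <- stats::runif(length(pick)) < 0.5
    repl <- ifelse(side_hi,
                   hi + stats::runif(length(pick), 0.05, 0.5) * span,
                   lo - stats::runif(length(pick), 0.05, 0.5) * span)
    rec <- data.frame(subject_id = out$subject_id[pick],
                      time_hr = out$time_hr[pick], channel = ch,
                      original = out$value[pick], value = repl,
                      stringsAsFactors = FALSE)
    out$value[pick] <- repl
  }
  list(vitals = out, outliers = rec)
}
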