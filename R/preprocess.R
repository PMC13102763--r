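## Preprocessing protocol: plausibility filter -> winsorize -> hourly
## aggregate -> impute/exclude -> standardize. Order is fixed; the filter and
## winsorization stages are idempotent on their own output.

#' Default plausibility ranges for the six vital-sign channels
#'
#' Inclusive clinical QC bounds; values outside are set to missing. Defaults
#' follow common critical-care range checks and are fully config-overridable.
#'
#' @return Data frame with columns `channel`, `lower`, `upper`.
#' @export
default_plausibility <- function() {
  data.frame(
    channel = VITAL_CHANNELS,
    lower = c(20, 4, 40, 20, 30, 50),
    upper = c(250, 60, 300, 200, 250, 100),
    stringsAsFactors = FALSE)
}

#' Plausibility filter
#'
#' Keeps a value iff `lower <= v <= upper` for its channel (bounds inclusive);
#' out-of-range values are set to missing and counted per channel.
#'
#' @param vitals Long vitals table (`subject_id`, `time_hr`, `channel`,
#'   `value`).
#' @param ranges Plausibility ranges as from [default_plausibility()].
#' @return List with `vitals` (filtered table, implausible rows dropped),
#'   `flagged` (the offending rows), and `report` (per-channel removal
#'   counts).
#' @export
plausibility_filter <- function(vitals, ranges = default_plausibility()) {
  miss <- setdiff(unique(vitals$channel), ranges$channel)
  if (length(miss))
    stop_input("no plausibility range defined for channel(s): ",
               paste(miss, collapse = ", "))
  if (any(ranges$lower >= ranges$upper))
    stop_input("plausibility ranges must satisfy lower < upper")
  i <- match(vitals$channel, ranges$channel)
  bad <- !(vitals$value >= ranges$lower[i] & vitals$value <= ranges$upper[i])
  bad[is.na(bad)] <- TRUE
  counts <- table(factor(vitals$channel[bad], levels = ranges$channel))
  list(vitals = vitals[!bad, , drop = FALSE],
       flagged = vitals[bad, , drop = FALSE],
       report = data.frame(channel = ranges$channel,
                           removed = as.integer(counts),
                           stringsAsFactors = FALSE))
}

#' Winsorize a numeric vector at empirical quantiles
#'
#' Values below the `lower_q` quantile are set to it and values above the
#' `upper_q` quantile are set to it. Quantiles use linear interpolation
#' between order statistics (R type 7), the documented convention: on the
#' equally spaced grid 0..100, the 1st/99th percentiles are exactly 1 and 99.
#'
#' @param x Numeric vector (NAs passed through).
#' @param lower_q,upper_q Quantile probabilities, defaults 0.01 and 0.99.
#' @param bounds Optional fixed `c(lower, upper)` clipping bounds (e.g. the
#'   bounds a previous run stored); when supplied no quantiles are computed,
#'   making re-application exactly idempotent.
#' @return Clipped vector with attributes `lower`/`upper` holding the bounds.
#' @export
winsorize <- function(x, lower_q = 0.01, upper_q = 0.99, bounds = NULL) {
  ok <- is.finite(x)
  if (sum(ok) == 0) {
    warning("winsorize: no finite values; returning input unchanged")
    return(x)
  }
  if (sum(ok) < 2) {
    warning("winsorize: fewer than 2 finite values; returning input unchanged")
    return(x)
  }
  q <- bounds %||%
    stats::quantile(x[ok], c(lower_q, upper_q), type = 7, names = FALSE)
  out <- pmin(pmax(x, q[1]), q[2])
  attr(out, "lower") <- q[1]
  attr(out, "upper") <- q[2]
  out
}

# Winsorize raw observations per channel across the cohort (before hourly
# averaging, so a single artifactual spike cannot contaminate an hourly mean).
winsorize_vitals <- function(vitals, lower_q = 0.01, upper_q = 0.99) {
  bounds <- data.frame(channel = character(), lower = numeric(),
                       upper = numeric(), stringsAsFactors = FALSE)
  for (ch in unique(vitals$channel)) {
    i <- vitals$channel == ch
    w <- winsorize(vitals$value[i], lower_q, upper_q)
    vitals$value[i] <- as.numeric(w)
    bounds <- rbind(bounds, data.frame(channel = ch,
                                       lower = attr(w, "lower"),
                                       upper = attr(w, "upper")))
  }
  list(vitals = vitals, bounds = bounds)
}

#' Aggregate raw vitals to an hourly grid
#'
#' Each cell of the subject x channel x hour grid is the arithmetic mean of
#' the observations falling in the half-open hour bin `[h, h+1)`, `h = 0..11`
#' (hour 0 = ICU admission). Empty cells are missing; observations at
#' `time_hr >= horizon` are ignored.
#'
#' @param vitals Long vitals table.
#' @param horizon Number of hourly bins (default 12).
#' @return A numeric matrix `N x (6 * horizon)` of class `hourly_grids`;
#'   columns are channel-major (`HR.0 ... HR.11, RR.0, ...`), rownames are
#'   subject ids. Missing cells are `NA`.
#' @export
hourly_aggregate <- function(vitals, horizon = 12L) {
  unknown <- setdiff(unique(vitals$channel), VITAL_CHANNELS)
  if (length(unknown)) {
    row <- which(vitals$channel %in% unknown)[1]
    stop_input("unknown channel '", vitals$channel[row], "' at input row ", row)
  }
  if (any(vitals$time_hr < 0)) stop_input("observation times must be >= 0")
  keep <- vitals$time_hr < horizon
  v <- vitals[keep, , drop = FALSE]
  subjects <- sort(unique(vitals$subject_id))
  si <- match(v$subject_id, subjects)
  ci <- match(v$channel, VITAL_CHANNELS)
  hi <- floor(v$time_hr)
  col <- (ci - 1L) * horizon + hi + 1L
  idx <- (si - 1L) * (length(VITAL_CHANNELS) * horizon) + col
  ncell <- length(subjects) * length(VITAL_CHANNELS) * horizon
  sums <- rowsum(v$value, idx)
  cnts <- rowsum(rep(1, nrow(v)), idx)
  flat <- rep(NA_real_, ncell)
  at <- as.integer(rownames(sums))
  flat[at] <- sums / cnts
  m <- matrix(flat, nrow = length(subjects), byrow = TRUE,
              dimnames = list(subjects,
                              paste(rep(VITAL_CHANNELS, each = horizon),
                                    0:(horizon - 1), sep = ".")))
  structure(m, horizon = as.integer(horizon), class = c("hourly_grids", "matrix"))
}

# Impute one channel's 12-hour vector in place, or return the exclusion
# reason. Rule priority: interior gaps of run length 1-2 with observed
# neighbors on both sides -> linear interpolation; longer interior gaps and
# trailing runs (length <= 4) -> last observation carried forward; leading
# runs -> next observation carried backward; any run > 4 -> exclusion.
impute_channel <- function(y, max_gap = 4L) {
  if (all(is.na(y))) return(list(y = y, excluded = "empty_channel"))
  r <- rle(is.na(y))
  if (any(r$lengths[r$values] > max_gap))
    return(list(y = y, excluded = "long_gap"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    a <- starts[j]; b <- ends[j]; len <- b - a + 1L
    left <- if (a > 1L) y[a - 1L] else NA_real_
    right <- if (b < length(y)) y[b + 1L] else NA_real_
    if (is.na(left)) {
      y[a:b] <- right                       # leading run: backfill
    } else if (is.na(right)) {
      y[a:b] <- left                        # trailing run: LOCF
    } else if (len <= 2L) {
      y[a:b] <- left + (right - left) * seq_len(len) / (len + 1L)
    } else {
      y[a:b] <- left                        # interior run of 3-4: LOCF
    }
  }
  list(y = y, excluded = NA_character_)
}

#' Impute hourly grids or exclude subjects
#'
#' Applies the gap-handling protocol per channel: subjects with any run of
#' more than 4 consecutive missing hours on any channel are excluded
#' (`"long_gap"`), as are subjects with a channel that was never observed
#' (`"empty_channel"`). Interior gaps of 1-2 h with observed neighbors are
#' linearly interpolated; remaining interior and trailing runs carry the last
#' observation forward; leading runs carry the first observation backward.
#' Observed cells are never altered; retained grids are complete.
#'
#' @param grids `hourly_grids` matrix from [hourly_aggregate()].
#' @return List with `grids` (complete matrix of retained subjects),
#'   `imputed_mask` (logical matrix, TRUE where a cell was filled), and
#'   `exclusions` (data frame `subject_id`, `reason`).
#' @export
impute_grid <- function(grids) {
  horizon <- attr(grids, "horizon") %||% 12L
  V <- length(VITAL_CHANNELS)
  out <- unclass(grids)
  mask <- is.na(out)
  reason <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (v in seq_len(V)) {
      cols <- (v - 1L) * horizon + seq_len(horizon)
      res <- impute_channel(out[i, cols])
      if (!is.na(res$excluded)) { reason[i] <- res$excluded; break }
      out[i, cols] <- res$y
    }
  }
  keep <- is.na(reason)
  exclusions <- data.frame(
    subject_id = rownames(out)[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  g <- structure(out[keep, , drop = FALSE], horizon = horizon,
                 class = c("hourly_grids", "matrix"))
  list(grids = g, imputed_mask = mask[keep, , drop = FALSE],
       exclusions = exclusions)
}

#' Standardize hourly grids to pooled Z-scores
#'
#' Per channel, the mean and SD are pooled over all retained subject-hours;
#' each cell becomes `(value - mean) / SD`. The returned parameters support
#' the inverse transform of fitted trajectories back to native units.
#'
#' @param grids Complete `hourly_grids` matrix (post-imputation).
#' @return List with `grids` (standardized matrix) and `scaling` (data frame
#'   `channel`, `mean`, `sd`).
#' @export
standardize_grids <- function(grids) {
  horizon <- attr(grids, "horizon") %||% 12L
  out <- unclass(grids)
  scaling <- data.frame(channel = VITAL_CHANNELS, mean = NA_real_,
                        sd = NA_real_, stringsAsFactors = FALSE)
  for (v in seq_along(VITAL_CHANNELS)) {
    cols <- (v - 1L) * horizon + seq_len(horizon)
    vals <- out[, cols]
    m <- mean(vals); s <- stats::sd(as.numeric(vals))
    if (!is.finite(s) || s == 0)
      stop_input("channel ", VITAL_CHANNELS[v],
                 " has zero pooled SD; cannot standardize")
    out[, cols] <- (vals - m) / s
    scaling$mean[v] <- m; scaling$sd[v] <- s
  }
  list(grids = structure(out, horizon = horizon,
                         class = c("hourly_grids", "matrix")),
       scaling = scaling)
}

#' Full preprocessing protocol for raw vitals
#'
#' Runs the fixed pipeline: plausibility filter, winsorization of raw
#' observations per channel (1st/99th percentiles), hourly aggregation over
#' the first `horizon` hours, gap imputation with exclusion of subjects with
#' more than 4 consecutive missing hours, and Z-score standardization.
#'
#' @param vitals Long vitals table (`subject_id`, `time_hr`, `channel`,
#'   `value`).
#' @param ranges Plausibility ranges ([default_plausibility()]).
#' @param horizon Hours of the trajectory window (default 12).
#' @param winsor_q Winsorization probabilities, default `c(0.01, 0.99)`.
#' @return Object of class `vital_grids`: list with standardized grids `z`,
#'   native-unit imputed grids `raw`, `imputed_mask`, `scaling`,
#'   `exclusions`, `plausibility_report`, `winsor_bounds`, `subjects`.
#' @export
preprocess_vitals <- function(vitals, ranges = default_plausibility(),
                              horizon = 12L, winsor_q = c(0.01, 0.99)) {
  n_in <- length(unique(vitals$subject_id))
  pf <- plausibility_filter(vitals, ranges)
  wz <- winsorize_vitals(pf$vitals, winsor_q[1], winsor_q[2])
  grids0 <- hourly_aggregate(wz$vitals, horizon)
  # subjects whose every observation was filtered out never reach the grid
  lost <- setdiff(unique(vitals$subject_id), rownames(grids0))
  imp <- impute_grid(grids0)
  if (length(lost))
    imp$exclusions <- rbind(
      data.frame(subject_id = as.character(lost), reason = "empty_channel",
                 stringsAsFactors = FALSE),
      imp$exclusions)
  std <- standardize_grids(imp$grids)
  structure(list(
    z = std$grids, raw = imp$grids, imputed_mask = imp$imputed_mask,
    scaling = std$scaling, exclusions = imp$exclusions,
    plausibility_report = pf$report, winsor_bounds = wz$bounds,
    subjects = rownames(imp$grids), n_input = n_in,
    horizon = as.integer(horizon)), class = "vital_grids")
}

#' @export
print.vital_grids <- function(x, ...) {
  cat("Preprocessed vital-sign grids\n")
  cat("  subjects retained:", length(x$subjects),
      " excluded:", nrow(x$exclusions), "\n")
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  cat("  channels:", paste(VITAL_CHANNELS, collapse = ", "),
      " hours: 0..", x$horizon - 1L, "\n", sep = "")
  invisible(x)
}
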