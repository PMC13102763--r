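## End-to-end orchestration: simulate -> preprocess -> trajectory fit ->
## survival contrasts -> spline dose-response -> safe zones, with one root
## seed, count reconciliation, and optional on-disk stage outputs.

#' Drop cohort columns with excessive missingness
#'
#' Removes columns whose missing fraction strictly exceeds `threshold`
#' (default 30%). Identifier, outcome, and cluster columns are protected: a
#' protected column above the threshold is a hard error.
#'
#' @param data Cohort data frame.
#' @param threshold Maximum tolerated missing fraction (strict `>` rule).
#' @param protect Columns that must never be dropped.
#' @return List: `data` (reduced table) and `report` (data frame `column`,
#'   `missing_frac`, `dropped`).
#' @export
drop_sparse_columns <- function(data, threshold = 0.30,
                                protect = c("subject_id", "cluster",
                                            grep("^(icu_|time_|event_)",
                                                 names(data), value = TRUE))) {
  if (threshold <= 0 || threshold > 1) stop_input("threshold must be in (0, 1]")
  frac <- vapply(data, function(col) mean(is.na(col)), numeric(1))
  over <- frac > threshold
  bad_protected <- intersect(names(data)[over], protect)
  if (length(bad_protected))
    stop_input("protected column(s) above missingness threshold: ",
               paste(bad_protected, collapse = ", "))
  drop <- over & !(names(data) %in% protect)
  list(data = data[!drop],
       report = data.frame(column = names(data), missing_frac = frac,
                           dropped = drop, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Run the full trajectory-to-targets pipeline
#'
#' Executes, from one root seed: cohort simulation with missingness and
#' outlier injection, the preprocessing protocol, group-number selection and
#' backward order elimination for the multi-trajectory model, Cox cluster
#' contrasts (crude / Model 1 / Model 2 at the ICU, 28-, 90- and 365-day
#' horizons), covariate-adjusted survival curves, restricted-cubic-spline
#' dose-response for every blood gas parameter within the high-risk cluster,
#' and random-forest partial-dependence safe zones. The high-risk cluster is
#' the one with the highest ICU mortality among modal assignments; the
#' reference cluster is the one with the lowest.
#'
#' @param config A [traj_config()]; its defaults define the study scenario.
#' @param seed Root seed; every stage seed is derived from it.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as CSV plus a JSON manifest (and the latent truth as a separate
#'   sidecar never joined into analysis inputs).
#' @param K_range Candidate group counts for selection.
#' @param n_starts EM initializations per fit.
#' @param delta Safe-zone threshold fraction of the PD range.
#' @param rf_spec [risk_model_spec()] for the per-parameter forests.
#' @param boot Bootstrap resamples for adjusted-survival bands.
#' @param prune Run backward elimination of polynomial orders after
#'   selection.
#' @return Object of class `traj_pipeline` with all stage results and a
#'   `manifest` (config echo, derived seeds, per-stage record counts).
#' @export
run_trajectory_pipeline <- function(config = default_scenario(),
                                    seed = 20260101L, out_dir = NULL,
                                    K_range = 1:6, n_starts = 3L,
                                    delta = 0.2,
                                    rf_spec = risk_model_spec(),
                                    boot = 100L, prune = TRUE) {
  seeds <- derive_seeds(seed, 6L)
  config$seed <- seeds[1]

  sim <- simulate_cohort(config)
  mis <- inject_missingness(sim$vitals, config)
  out <- inject_outliers(mis$vitals, config)
  grids <- preprocess_vitals(out$vitals, config$plausibility)

  sparse <- drop_sparse_columns(sim$cohort)
  cohort <- sparse$data

  sel <- select_gbmtm(grids, K_range = K_range, n_starts = n_starts,
                      seed = seeds[2])
  fit <- if (prune && sel$K >= 1L) {
    pr <- prune_orders(grids, K = sel$K, n_starts = n_starts, seed = seeds[2])
    pr$fit
  } else sel$best
  labels <- data.frame(subject_id = grids$subjects,
                       cluster = fit$labels, stringsAsFactors = FALSE)

  records <- merge(cohort, labels,
                   by.x = "subject_id", by.y = "subject_id", sort = TRUE)
  records <- records[order(as.integer(records$subject_id)), , drop = FALSE]

  icu_rate <- tapply(records$icu_event, records$cluster, mean)
  high_risk <- as.integer(names(icu_rate)[which.max(icu_rate)])
  reference <- as.integer(names(icu_rate)[which.min(icu_rate)])

  cox <- list()
  for (h in c("icu", "28", "90", "365"))
    for (m in c("crude", "model1", "model2"))
      cox[[paste(h, m, sep = "_")]] <-
        cox_contrasts(records, horizon = h, model = m, reference = reference)
  cox_table <- do.call(rbind, lapply(names(cox), function(nm) {
    t <- cox[[nm]]$table
    t <- t[grepl("^cluster", t$term), , drop = FALSE]
    cbind(horizon = sub("_.*", "", nm), model = sub(".*_", "", nm), t)
  }))

  adj <- adjusted_survival(records, horizon = 365, boot = boot,
                           seed = seeds[3])

  hr_records <- records[records$cluster == high_risk, , drop = FALSE]
  gas <- config$gas_params$param
  rcs_fits <- list()
  for (p in gas)
    rcs_fits[[p]] <- fit_rcs_cox(hr_records, p)
  nonlin <- nonlinearity_report(rcs_fits)

  rf_models <- list(); profiles <- list(); zones <- list()
  for (j in seq_along(gas)) {
    sp <- rf_spec
    sp$seed <- seeds[4] + j
    rf_models[[gas[j]]] <- train_risk_model(hr_records, gas[j], spec = sp)
    profiles[[gas[j]]] <- partial_dependence(rf_models[[gas[j]]])
    zones[[gas[j]]] <- extract_safe_zone(profiles[[gas[j]]], delta = delta)
  }
  units <- stats::setNames(config$gas_params$units, config$gas_params$param)
  zone_table <- safe_zone_report(zones, units = units)

  n_excl <- nrow(grids$exclusions)
  manifest <- list(
    package_version = as.character(utils::packageVersion("trajtargets")),
    root_seed = seed, stage_seeds = seeds,
    n_subjects_input = config$n_subjects,
    n_retained = length(grids$subjects),
    n_excluded = n_excl,
    exclusions_by_reason = as.list(table(grids$exclusions$reason)),
    chosen_K = sel$K, high_risk_cluster = high_risk,
    reference_cluster = reference, delta = delta,
    config = list(n_subjects = config$n_subjects, mixing = config$mixing,
                  missing_rate = config$missing_rate,
                  long_gap_rate = config$long_gap_rate,
                  outlier_rate = config$outlier_rate,
                  hazard_shape = config$hazard_shape,
                  hazard_scale = config$hazard_scale,
                  group_loghr = config$group_loghr,
                  censor_rate = config$censor_rate,
                  generator_seed = config$seed))
  stopifnot(manifest$n_subjects_input == manifest$n_retained + manifest$n_excluded)

  res <- structure(list(
    config = config, manifest = manifest, truth = sim$truth,
    grids = grids, selection = sel, fit = fit, labels = labels,
    records = records, cox = cox, cox_table = cox_table, adjusted = adj,
    high_risk = high_risk, reference = reference,
    rcs = rcs_fits, nonlinearity = nonlin,
    rf = rf_models, pd_profiles = profiles, zones = zones,
    zone_table = zone_table, sparse_report = sparse$report),
    class = "traj_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Serialize every stage table; deterministic content (no timestamps).
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  g <- res$grids
  horizon <- g$horizon
  long <- data.frame(
    subject_id = rep(g$subjects, times = ncol(g$z)),
    channel = rep(rep(VITAL_CHANNELS, each = horizon), each = nrow(g$z)),
    hour = rep(rep(0:(horizon - 1), length(VITAL_CHANNELS)), each = nrow(g$z)),
    value = as.numeric(g$z),
    imputed = as.integer(res$grids$imputed_mask))
  wcsv(long, "grids.csv")
  wcsv(g$exclusions, "exclusions.csv")
  wcsv(g$scaling, "standardization.csv")
  wcsv(res$selection$table, "selection_table.csv")
  post <- data.frame(subject_id = g$subjects, res$fit$W,
                     label = res$fit$labels)
  names(post) <- c("subject_id", paste0("w_", seq_len(res$fit$K)), "label")
  wcsv(post, "posteriors.csv")
  wcsv(res$cox_table, "cox_results.csv")
  wcsv(res$adjusted$curves, "adjusted_curves.csv")
  rcsc <- do.call(rbind, lapply(res$rcs, function(f)
    cbind(param = f$param, f$curve)))
  wcsv(rcsc, "rcs_curves.csv")
  wcsv(res$nonlinearity, "nonlinearity.csv")
  pdp <- do.call(rbind, lapply(names(res$pd_profiles), function(p)
    data.frame(param = p, res$pd_profiles[[p]])))
  wcsv(pdp, "pd_profiles.csv")
  wcsv(res$zone_table, "safe_zones.csv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(group = res$truth$group,
         gas_intervals = res$truth$gas_intervals),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.traj_pipeline <- function(x, ...) {
  cat("trajectory-to-targets pipeline run\n")
  m <- x$manifest
  cat(sprintf("  subjects: %d input, %d retained, %d excluded\n",
              m$n_subjects_input, m$n_retained, m$n_excluded))
  cat(sprintf("  chosen K = %d; high-risk cluster %d (reference %d)\n",
              m$chosen_K, m$high_risk_cluster, m$reference_cluster))
  cat("  safe zones:\n")
  for (z in x$zones) cat("    ", format(z), "\n")
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Markdown summary of a pipeline run: the selection table, classification
#' diagnostics against the conventional adequacy thresholds (entropy > 0.7,
#' AvePP > 0.7, OCC > 5, shares >= 5%), the cluster hazard-ratio table, the
#' nonlinearity table, and the safe zones. Every number is re-derivable from
#' the stage outputs.
#'
#' @param x A `traj_pipeline` result.
#' @return Character vector of markdown lines (invisibly printed with
#'   `cat`).
#' @export
pipeline_report <- function(x) {
  d <- gbmtm_diagnostics(x$fit)
  thr <- data.frame(
    check = c("entropy > 0.7", "min AvePP > 0.7", "min OCC > 5",
              "min share >= 5%"),
    value = c(d$entropy, min(d$avepp, na.rm = TRUE), min(d$occ),
              min(d$shares)),
    pass = c(d$entropy > 0.7, min(d$avepp, na.rm = TRUE) > 0.7,
             min(d$occ) > 5, all(d$shares >= 0.05)))
  lines <- c(
    "# Trajectory-to-targets run report", "",
    sprintf("Subjects: %d input / %d retained / %d excluded.",
            x$manifest$n_subjects_input, x$manifest$n_retained,
            x$manifest$n_excluded),
    sprintf("Chosen K = %d; high-risk cluster %d, reference cluster %d.",
            x$manifest$chosen_K, x$high_risk, x$reference), "",
    "## Classification adequacy",
    sprintf("- %s: %.3f (%s)", thr$check, thr$value,
            ifelse(thr$pass, "pass", "FAIL")), "",
    "## Cluster hazard ratios (vs reference)",
    sprintf("- %s / %s: %s HR %.2f (%.2f, %.2f)",
            x$cox_table$horizon, x$cox_table$model, x$cox_table$term,
            x$cox_table$HR, x$cox_table$lo, x$cox_table$hi), "",
    "## Nonlinearity of blood gas dose-response",
    sprintf("- %s: chi-square %.2f (df %d), p = %.3g%s",
            x$nonlinearity$param, x$nonlinearity$chisq, x$nonlinearity$df,
            x$nonlinearity$p,
            ifelse(x$nonlinearity$nonlinear, " (nonlinear)", "")), "",
    "## Safe zones",
    vapply(x$zones, function(z)
      sprintf("- %s (delta = %.2f)", format(z), z$delta), character(1)))
  invisible(lines)
}
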