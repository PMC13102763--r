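## Restricted cubic spline dose-response: Harrell-convention basis, Cox
## models of blood gas value vs ICU mortality within a cluster, a joint Wald
## test of nonlinearity, and the hazard-ratio curve against a reference value.

#' Restricted cubic spline basis (Harrell convention)
#'
#' With knots `t_1 < ... < t_k`, returns the linear term plus `k - 2`
#' nonlinear columns
#' `term_j(x) = [(x - t_j)+^3 - (x - t_{k-1})+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2`,
#' which is 0 for `x <= t_1` and linear in `x` beyond `t_k`.
#'
#' @param x Numeric vector.
#' @param knots At least 3 distinct knot locations.
#' @return Matrix with columns `x`, `x'`, `x''`, ... and attribute `knots`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(knots)
  if (length(knots) < 3L) stop_input("need at least 3 knots")
  if (anyDuplicated(knots)) stop_input("knots must be distinct")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1L)
  out[, 1] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                        pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                        pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
  }
  colnames(out) <- c("x", paste0("x", strrep("'", seq_len(k - 2L))))
  attr(out, "knots") <- knots
  out
}

#' Default knot placement
#'
#' Empirical quantiles at the standard positions: `(0.05, 0.35, 0.65, 0.95)`
#' for 4 knots, `(0.10, 0.50, 0.90)` for 3, and
#' `(0.05, 0.275, 0.50, 0.725, 0.95)` for 5.
#'
#' @param x Numeric vector with at least 20 distinct finite values.
#' @param k Number of knots (3, 4 or 5).
#' @return Numeric vector of knot locations.
#' @export
default_knots <- function(x, k = 4L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 20L)
    stop_input("need at least 20 distinct values to place knots")
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop_input("k must be 3, 4 or 5"))
  as.numeric(stats::quantile(x, probs, type = 7, names = FALSE))
}

#' Cox dose-response with a restricted cubic spline
#'
#' Models the log hazard of ICU mortality as a restricted cubic spline in one
#' blood gas parameter plus adjustment covariates (default age, sex, SOFA),
#' within the supplied records (typically the high-risk cluster). Returns the
#' hazard-ratio curve `HR(x) = exp(f(x) - f(x_ref))` with delta-method 95%
#' bands against the reference value (default: the median), and the joint
#' Wald test that all nonlinear coefficients are zero (`df = k - 2`).
#'
#' @param data Data frame with `icu_time`, `icu_event`, the gas column, and
#'   covariates.
#' @param param Name of the blood gas column.
#' @param covars Adjustment covariates.
#' @param knots Knot locations (default: [default_knots()] on the data).
#' @param k Number of knots when `knots` is NULL.
#' @param x_ref Reference value where HR = 1 (default: median of `param`).
#' @param grid_n Points of the HR curve grid (1st-99th percentile span).
#' @return Object of class `rcs_fit`: `curve` (x, HR, lo, hi),
#'   `nonlinearity` (chi-square, df, p), `knots`, `x_ref`, the Cox `fit`.
#' @export
fit_rcs_cox <- function(data, param, covars = c("age", "sex", "sofa"),
                        knots = NULL, k = 4L, x_ref = NULL, grid_n = 100L) {
  x <- data[[param]]
  if (is.null(x)) stop_input("no column '", param, "' in data")
  if (is.null(knots)) knots <- default_knots(x, k)
  if (is.null(x_ref)) x_ref <- stats::median(x, na.rm = TRUE)
  B <- rcs_basis(x, knots)
  nb <- ncol(B)
  covars <- covars[covars %in% names(data)]
  df <- data.frame(.time = data$icu_time, .event = data$icu_event, B,
                   data[covars], check.names = FALSE)
  spl_names <- colnames(B)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(c(sprintf("`%s`", spl_names), covars), collapse = " + ")))
  fit <- tryCatch(survival::coxph(fml, data = df, ties = "efron"),
                  error = function(e)
                    stop_input("spline Cox fit failed (", conditionMessage(e),
                               "); consider fewer knots"))
  beta <- stats::coef(fit)[seq_len(nb)]
  Vc <- stats::vcov(fit)[seq_len(nb), seq_len(nb), drop = FALSE]

  nl_idx <- 2:nb
  w <- tryCatch(
    as.numeric(t(beta[nl_idx]) %*%
                 solve(Vc[nl_idx, nl_idx, drop = FALSE], beta[nl_idx])),
    error = function(e) NA_real_)
  nonlin <- data.frame(chisq = w, df = nb - 1L,
                       p = stats::pchisq(w, nb - 1L, lower.tail = FALSE))

  qs <- stats::quantile(x, c(0.01, 0.99), na.rm = TRUE, names = FALSE)
  grid <- sort(unique(c(seq(qs[1], qs[2], length.out = grid_n), x_ref)))
  Dg <- rcs_basis(grid, knots) -
    matrix(rcs_basis(x_ref, knots), length(grid), nb, byrow = TRUE)
  f <- as.numeric(Dg %*% beta)
  se <- sqrt(pmax(rowSums((Dg %*% Vc) * Dg), 0))
  curve <- data.frame(x = grid, HR = exp(f),
                      lo = exp(f - 1.96 * se), hi = exp(f + 1.96 * se))
  structure(list(curve = curve, nonlinearity = nonlin, knots = knots,
                 x_ref = x_ref, param = param, fit = fit,
                 coef = beta, vcov = Vc),
            class = "rcs_fit")
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat(sprintf("RCS Cox dose-response for %s (%d knots; reference %.3g)\n",
              x$param, length(x$knots), x$x_ref))
  cat(sprintf("  nonlinearity: chi-square %.2f on %d df, p = %s\n",
              x$nonlinearity$chisq, x$nonlinearity$df,
              format.pval(x$nonlinearity$p, digits = 3)))
  invisible(x)
}

#' @export
plot.rcs_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$x, cv$HR, type = "l", lwd = 2, log = "y",
                 xlab = x$param, ylab = "hazard ratio", ...)
  graphics::polygon(c(cv$x, rev(cv$x)), c(cv$lo, rev(cv$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Tabulate nonlinearity tests across blood gas parameters
#'
#' One row per fitted parameter: Wald chi-square, df, p-value, and the flag
#' at the 0.05 level. No multiplicity correction is applied by default;
#' `bonferroni = TRUE` divides the level by the number of parameters.
#'
#' @param fits Named list of [fit_rcs_cox()] results.
#' @param alpha Significance level.
#' @param bonferroni Apply a Bonferroni-corrected level instead.
#' @return Data frame `param`, `chisq`, `df`, `p`, `nonlinear`.
#' @export
nonlinearity_report <- function(fits, alpha = 0.05, bonferroni = FALSE) {
  if (length(fits) == 0)
    return(data.frame(param = character(), chisq = numeric(),
                      df = integer(), p = numeric(), nonlinear = logical()))
  level <- if (bonferroni) alpha / length(fits) else alpha
  do.call(rbind, lapply(fits, function(f)
    data.frame(param = f$param, chisq = f$nonlinearity$chisq,
               df = f$nonlinearity$df, p = f$nonlinearity$p,
               nonlinear = is.finite(f$nonlinearity$p) &
                 f$nonlinearity$p < level,
               row.names = NULL, stringsAsFactors = FALSE)))
}
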