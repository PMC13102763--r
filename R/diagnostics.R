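## Classification diagnostics and model selection for multi-trajectory fits:
## relative entropy, AvePP, OCC, the BIC/entropy/minimum-share selection rule,
## and backward elimination of polynomial orders.

#' Relative entropy of a posterior membership matrix
#'
#' `E = 1 - sum_i sum_g (-w_ig log w_ig) / (N log K)`, with `0 log 0 = 0`.
#' 1 means perfectly crisp classification, 0 maximal confusion. `K = 1`
#' returns 1 by convention (classification is vacuous).
#'
#' @param W Row-stochastic `N x K` posterior matrix.
#' @return Scalar in `[0, 1]`.
#' @export
relative_entropy <- function(W) {
  W <- as.matrix(W)
  if (any(abs(rowSums(W) - 1) > 1e-8))
    stop_input("rows of W must sum to 1")
  K <- ncol(W)
  if (K == 1L) return(1)
  h <- -W * log(W)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (nrow(W) * log(K))
}

#' Average posterior probability of assignment per group
#'
#' `AvePP_g` is the mean posterior membership probability `w_ig` among
#' subjects modally assigned to group `g`. Empty groups are reported as `NA`
#' with a warning.
#'
#' @param W Row-stochastic posterior matrix.
#' @param labels Modal assignments (defaults to row-wise argmax of `W`).
#' @return Numeric vector of length K.
#' @export
avepp <- function(W, labels = NULL) {
  W <- as.matrix(W)
  if (is.null(labels)) labels <- max.col(W, ties.method = "first")
  K <- ncol(W)
  out <- rep(NA_real_, K)
  for (g in seq_len(K)) {
    i <- labels == g
    if (!any(i)) {
      warning("group ", g, " is empty; AvePP undefined")
      next
    }
    out[g] <- mean(W[i, g])
  }
  out
}

#' Odds of correct classification
#'
#' `OCC_g = [AvePP_g / (1 - AvePP_g)] / [pi_g / (1 - pi_g)]`: the posterior
#' odds of correct assignment relative to the prior (mixing) odds. Equals 1
#' when assignment is no better than chance; values above 5 conventionally
#' indicate adequate assignment. `AvePP = 1` returns `Inf`.
#'
#' @param avepp_g Per-group average posterior probabilities in `(0, 1]`.
#' @param pi_g Mixing proportions in `(0, 1)`.
#' @return Numeric vector of OCC values.
#' @export
occ <- function(avepp_g, pi_g) {
  if (any(pi_g <= 0 | pi_g >= 1, na.rm = TRUE))
    stop_input("mixing proportions must lie strictly inside (0, 1)")
  ifelse(avepp_g >= 1, Inf,
         (avepp_g / (1 - avepp_g)) / (pi_g / (1 - pi_g)))
}

#' Model-selection diagnostics for a fitted multi-trajectory model
#'
#' @param fit A [gbmtm()] fit.
#' @return List: `BIC`, `AIC`, `entropy`, modal group `shares`, per-group
#'   `avepp` and `occ`, and `eligible` — whether the fit satisfies the
#'   selection rule (entropy > 0.7 for K >= 2 and every modal share >= 5%).
#' @export
gbmtm_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "gbmtm"))
  shares <- tabulate(fit$labels, nbins = fit$K) / fit$N
  e <- relative_entropy(fit$W)
  ap <- suppressWarnings(avepp(fit$W, fit$labels))
  oc <- if (fit$K == 1L) Inf else suppressWarnings(occ(ap, fit$pi))
  eligible <- (fit$K == 1L || e > 0.7) && all(shares >= 0.05)
  list(BIC = fit$BIC, AIC = fit$AIC, entropy = e, shares = shares,
       avepp = ap, occ = oc, eligible = eligible)
}

#' Select the number of trajectory groups
#'
#' Fits the model for each candidate `K`, computes diagnostics, and applies
#' the selection rule: among models with relative entropy > 0.7 (K >= 2) and
#' every modal group share >= 5%, choose the lowest BIC; ties go to the
#' smaller K. If no model is eligible, the overall lowest-BIC model is
#' returned with a warning. Individual fit failures are recorded and skipped.
#'
#' @param x Grids accepted by [gbmtm()].
#' @param K_range Candidate group counts (default 1..6).
#' @param ... Passed to [gbmtm()] (orders, n_starts, tol, seed, ...).
#' @return Object of class `gbmtm_selection`: `table` (one row per K:
#'   loglik, k, BIC, AIC, entropy, min share, min AvePP, min OCC, eligible),
#'   `fits` (list), `K` (chosen), `best` (chosen fit).
#' @export
select_gbmtm <- function(x, K_range = 1:6, ...) {
  rows <- list(); fits <- list()
  for (K in K_range) {
    fit <- tryCatch(gbmtm(x, K = K, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("K = ", K, " failed: ", conditionMessage(fit))
      rows[[as.character(K)]] <- data.frame(
        K = K, loglik = NA, k = NA, BIC = NA, AIC = NA, entropy = NA,
        min_share = NA, min_avepp = NA, min_occ = NA, eligible = FALSE)
      next
    }
    d <- gbmtm_diagnostics(fit)
    fits[[as.character(K)]] <- fit
    rows[[as.character(K)]] <- data.frame(
      K = K, loglik = fit$loglik, k = fit$k, BIC = d$BIC, AIC = d$AIC,
      entropy = d$entropy, min_share = min(d$shares),
      min_avepp = min(d$avepp, na.rm = TRUE), min_occ = min(d$occ),
      eligible = d$eligible)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cand <- tab[tab$eligible & !is.na(tab$BIC), , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no model satisfied the eligibility rule; returning lowest BIC")
    cand <- tab[!is.na(tab$BIC), , drop = FALSE]
  }
  if (nrow(cand) == 0) stop_input("every candidate fit failed")
  chosen <- cand$K[order(cand$BIC, cand$K)][1]
  structure(list(table = tab, fits = fits, K = chosen,
                 best = fits[[as.character(chosen)]]),
            class = "gbmtm_selection")
}

#' @export
print.gbmtm_selection <- function(x, ...) {
  cat("Trajectory group-number selection (chosen K =", x$K, ")\n")
  tab <- x$table
  tab[, c("loglik", "BIC", "AIC")] <- round(tab[, c("loglik", "BIC", "AIC")], 1)
  tab[, c("entropy", "min_share", "min_avepp")] <-
    round(tab[, c("entropy", "min_share", "min_avepp")], 3)
  tab$min_occ <- round(tab$min_occ, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Backward elimination of polynomial orders
#'
#' Starts from cubic trajectories everywhere and repeatedly decrements, for
#' every (group, channel), the polynomial order whose current highest-order
#' coefficient is not significant (Wald `z = beta / SE` from the
#' weighted-least-squares covariance of the final M-step, `p >= alpha`),
#' refitting after each round. Stops when every retained highest-order term
#' is significant, when every order has reached 1, or after `max_rounds`
#' rounds (with a warning).
#'
#' @param x Grids accepted by [gbmtm()].
#' @param K Number of groups.
#' @param alpha Wald significance level for retaining the highest-order term.
#' @param max_rounds Oscillation guard (default 10).
#' @param ... Passed to [gbmtm()].
#' @return List: `fit` (the parsimonious fit), `orders` (final `K x V`
#'   matrix), `rounds` (elimination rounds performed).
#' @export
prune_orders <- function(x, K, alpha = 0.05, max_rounds = 10L, ...) {
  xm <- if (inherits(x, "vital_grids")) x$z else x
  horizon <- attr(xm, "horizon") %||% 12L
  V <- as.integer(ncol(xm) / horizon)
  orders <- matrix(3L, K, V)
  fit <- gbmtm(x, K = K, orders = orders, ...)
  rounds <- 0L
  repeat {
    drop_any <- FALSE
    for (g in seq_len(K)) for (v in seq_len(V)) {
      o <- orders[g, v]
      if (o <= 1L) next
      b <- fit$beta[g, v, o + 1L]; s <- fit$se[g, v, o + 1L]
      p <- 2 * stats::pnorm(-abs(b / s))
      if (is.na(p) || p >= alpha) {
        orders[g, v] <- o - 1L
        drop_any <- TRUE
      }
    }
    if (!drop_any) break
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      warning("order elimination stopped after ", max_rounds, " rounds")
      break
    }
    fit <- gbmtm(x, K = K, orders = orders, ...)
  }
  list(fit = fit, orders = orders, rounds = rounds)
}

#' Align estimated group labels with reference labels
#'
#' Searches all permutations of the estimated group indices for the one
#' maximizing agreement with a reference labeling — the standard guard
#' against label switching when validating against simulation truth.
#'
#' @param truth Reference labels in 1..K.
#' @param labels Estimated labels in 1..K.
#' @return List: `accuracy` (agreement under the best permutation), `perm`
#'   (the permutation applied to `labels`), `labels` (permuted labels).
#' @export
match_labels <- function(truth, labels) {
  K <- max(truth, labels)
  perms <- all_perms(K)
  best_acc <- -1; best_perm <- seq_len(K)
  for (p in perms) {
    acc <- mean(p[labels] == truth)
    if (acc > best_acc) { best_acc <- acc; best_perm <- p }
  }
  list(accuracy = best_acc, perm = best_perm, labels = best_perm[labels])
}

all_perms <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    sub <- all_perms(K - 1L)
    for (s in sub) {
      rest <- seq_len(K)[-i]
      out[[length(out) + 1L]] <- c(i, rest[s])
    }
  }
  out
}
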