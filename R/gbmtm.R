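## Group-based multi-trajectory model: a finite mixture of per-channel
## polynomial regressions over the hourly grid, fitted by EM. Channels and
## hours are conditionally independent given latent group membership:
##   y_{ivt} | group g ~ N(sum_p beta_{gvp} * tc^p, sigma_{gv}^2)
## with tc the hour index centered at the window midpoint.

# Centered-time design matrix for a polynomial of given order.
time_design <- function(horizon = 12L, order = 3L) {
  tc <- (seq_len(horizon) - 1) - (horizon - 1) / 2
  m <- outer(tc, 0:order, `^`)
  colnames(m) <- c("intercept", "linear", "quadratic", "cubic")[seq_len(order + 1)]
  m
}

# Free-parameter count: mixing + polynomial coefficients + one residual
# variance per (group, channel).
#' Free-parameter count of a multi-trajectory model
#'
#' `k = (K - 1) + sum(orders + 1) + K * V`: mixing proportions, polynomial
#' coefficients, and one residual variance per (group, channel).
#'
#' @param K Number of groups.
#' @param orders `K x V` matrix (or scalar) of polynomial orders in 1..3.
#' @param V Number of channels (default 6).
#' @return Integer parameter count.
#' @export
count_params <- function(K, orders, V = length(VITAL_CHANNELS)) {
  if (length(orders) == 1L) orders <- matrix(orders, K, V)
  stopifnot(all(orders >= 1), all(orders <= 3), all(dim(orders) == c(K, V)))
  (K - 1L) + sum(orders + 1L) + K * V
}

#' Penalized likelihood criteria
#'
#' `BIC = -2 loglik + k log N` (N = number of subjects) and
#' `AIC = -2 loglik + 2 k`; lower is better.
#'
#' @param loglik Observed-data log-likelihood.
#' @param k Free-parameter count ([count_params()]).
#' @param N Number of subjects.
#' @return List with elements `BIC` and `AIC`.
#' @export
information_criteria <- function(loglik, k, N) {
  stopifnot(N >= 1)
  list(BIC = -2 * loglik + k * log(N), AIC = -2 * loglik + 2 * k)
}

#' Fit a group-based multi-trajectory model by EM
#'
#' Fits a `K`-group finite mixture of polynomial regressions jointly over the
#' six standardized vital-sign channels. The E-step computes posterior
#' membership probabilities in log space with a log-sum-exp guard; the M-step
#' solves per-(group, channel) weighted least squares with subject weights,
#' updates residual variances as weighted mean squared residuals (floored at
#' 1e-6), and mixing proportions as mean posteriors. The best of `n_starts`
#' initializations (k-means on the flattened grids, then perturbed k-means
#' centers) is returned.
#'
#' @param x A `vital_grids` object from [preprocess_vitals()] (its
#'   standardized grids are used), or a complete numeric matrix
#'   `N x (V * horizon)` with channel-major columns.
#' @param K Number of latent groups (`>= 1`).
#' @param orders Polynomial order per (group, channel): scalar or `K x V`
#'   matrix with entries in 1..3 (default cubic everywhere).
#' @param n_starts Number of random initializations.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Convergence tolerance on the observed-data log-likelihood.
#' @param seed Integer seed controlling initialization.
#' @return Object of class `gbmtm`: mixing proportions `pi`, coefficient
#'   array `beta` (`K x V x 4`, `NA` beyond each order), residual SDs `sigma`
#'   (`K x V`), posterior matrix `W`, modal `labels`, `loglik`, iteration
#'   `trace`, parameter count `k`, `BIC`/`AIC`, and `converged`.
#' @examples
#' cfg <- default_scenario(n_subjects = 120, seed = 7)
#' sim <- simulate_cohort(cfg)
#' grids <- preprocess_vitals(sim$vitals)
#' fit <- gbmtm(grids, K = 3, n_starts = 2, seed = 7)
#' fit
#' @export
gbmtm <- function(x, K, orders = 3L, n_starts = 3L, max_iter = 200L,
                  tol = 1e-6, seed = 1L) {
  scaling <- NULL
  if (inherits(x, "vital_grids")) { scaling <- x$scaling; x <- x$z }
  Y <- unclass(x)
  if (anyNA(Y)) stop_input("grids must be complete (impute first)")
  N <- nrow(Y)
  horizon <- attr(x, "horizon") %||% (ncol(Y) / length(VITAL_CHANNELS))
  V <- ncol(Y) / horizon
  if (V != round(V)) stop_input("column count is not a multiple of the horizon")
  V <- as.integer(V)
  if (K < 1L) stop_input("K must be >= 1")
  if (N < K) stop_input("need at least K subjects (N = ", N, ", K = ", K, ")")
  if (length(orders) == 1L) orders <- matrix(as.integer(orders), K, V)
  stopifnot(all(dim(orders) == c(K, V)), all(orders >= 1), all(orders <= 3))
  if (tol <= 0) stop_input("tol must be > 0")

  Xfull <- time_design(horizon, 3L)
  # per-order projector solve(X'X) X' and design, shared across groups and
  # channels; computed only for the orders actually requested
  proj <- vector("list", 3L)
  for (o in sort(unique(as.integer(orders)))) {
    X <- Xfull[, seq_len(o + 1), drop = FALSE]
    proj[[o]] <- list(X = X, H = solve(crossprod(X), t(X)),
                      XtXinv = solve(crossprod(X)))
  }

  set.seed(as.integer(seed))
  km <- tryCatch(stats::kmeans(Y, centers = K, nstart = 5, iter.max = 50),
                 error = function(e) NULL)
  centers0 <- if (!is.null(km)) km$centers else
    Y[sample.int(N, K), , drop = FALSE]

  best <- NULL
  for (s in seq_len(n_starts)) {
    centers <- if (s == 1L) centers0 else
      centers0 + matrix(stats::rnorm(length(centers0), 0, 0.5), K)
    d2 <- sapply(seq_len(K), function(g)
      rowSums(sweep(Y, 2, centers[g, ])^2))
    if (K == 1L) d2 <- matrix(d2, ncol = 1L)
    lab0 <- max.col(-d2, ties.method = "first")
    W <- matrix(1e-6, N, K); W[cbind(seq_len(N), lab0)] <- 1
    W <- W / rowSums(W)
    res <- tryCatch(
      em_run(Y, W, orders, proj, horizon, V, K, max_iter, tol),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (is.null(best) && s == n_starts) stop(res)
      next
    }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) stop_input("all EM starts failed")

  labels <- max.col(best$W, ties.method = "first")
  k <- count_params(K, orders, V)
  ic <- information_criteria(best$loglik, k, N)
  structure(list(
    pi = best$pi, beta = best$beta, sigma = best$sigma, se = best$se,
    W = best$W, labels = labels, loglik = best$loglik, trace = best$trace,
    converged = best$converged, iterations = length(best$trace),
    K = K, V = V, horizon = as.integer(horizon), orders = orders,
    N = N, k = k, BIC = ic$BIC, AIC = ic$AIC,
    scaling = scaling, seed = as.integer(seed), tol = tol, data = Y),
    class = "gbmtm")
}

# One EM run from initial responsibilities.
em_run <- function(Y, W, orders, proj, horizon, V, K, max_iter, tol) {
  N <- nrow(Y); D <- ncol(Y)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  pars <- mstep(Y, W, orders, proj, horizon, V, K)
  for (it in seq_len(max_iter)) {
    es <- estep(Y, pars, horizon, V, K)
    W <- es$W
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) && abs(es$loglik - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- es$loglik
    pars <- mstep(Y, W, orders, proj, horizon, V, K)
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  c(pars, list(W = W, loglik = trace[length(trace)], trace = trace,
               converged = converged))
}

estep <- function(Y, pars, horizon, V, K) {
  N <- nrow(Y); D <- ncol(Y)
  logd <- matrix(0, N, K)
  for (g in seq_len(K)) {
    mu <- pars$mu[g, ]
    s  <- pars$sigma_cell[g, ]
    R <- sweep(Y, 2, mu)
    logd[, g] <- -0.5 * (R^2 %*% (1 / s^2)) - sum(log(s)) -
      0.5 * D * log(2 * pi) + log(pars$pi[g])
  }
  ll_i <- row_logsumexp(logd)
  W <- exp(logd - ll_i)
  list(W = W, loglik = sum(ll_i))
}

mstep <- function(Y, W, orders, proj, horizon, V, K) {
  N <- nrow(Y)
  pi_g <- colMeans(W)
  ch_names <- if (V == length(VITAL_CHANNELS)) VITAL_CHANNELS else
    paste0("ch", seq_len(V))
  beta <- array(NA_real_, c(K, V, 4L),
                dimnames = list(NULL, ch_names,
                                c("intercept", "linear", "quadratic", "cubic")))
  se <- beta
  sigma <- matrix(NA_real_, K, V, dimnames = list(NULL, ch_names))
  mu <- matrix(NA_real_, K, ncol(Y))
  sigma_cell <- mu
  for (g in seq_len(K)) {
    w <- W[, g]; sw <- sum(w)
    if (sw < 1e-6)
      stop_input("degenerate component: group ", g,
                 " has vanishing total weight; try a smaller K")
    for (v in seq_len(V)) {
      cols <- (v - 1L) * horizon + seq_len(horizon)
      Yv <- Y[, cols, drop = FALSE]
      ybar <- as.numeric(crossprod(Yv, w)) / sw
      o <- orders[g, v]
      p <- proj[[o]]
      b <- as.numeric(p$H %*% ybar)
      fit <- as.numeric(p$X %*% b)
      sw2 <- as.numeric(crossprod(Yv^2, w))
      rss <- sum(sw2 - 2 * fit * (sw * ybar) + sw * fit^2)
      s2 <- max(rss / (horizon * sw), 1e-6)
      beta[g, v, seq_len(o + 1)] <- b
      se[g, v, seq_len(o + 1)] <- sqrt(s2 * diag(p$XtXinv) / sw)
      sigma[g, v] <- sqrt(s2)
      mu[g, cols] <- fit
      sigma_cell[g, cols] <- sqrt(s2)
    }
  }
  list(pi = pi_g, beta = beta, se = se, sigma = sigma, mu = mu,
       sigma_cell = sigma_cell)
}

#' @export
print.gbmtm <- function(x, ...) {
  cat("Group-based multi-trajectory model (", x$K, " group",
      if (x$K > 1) "s", ", ", x$V, " channels, ", x$horizon,
      " hourly bins)\n", sep = "")
  cat(sprintf("  log-likelihood %.2f on %d parameters (N = %d)\n",
              x$loglik, x$k, x$N))
  cat(sprintf("  BIC %.1f  AIC %.1f  %s after %d iterations\n", x$BIC, x$AIC,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
logLik.gbmtm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$N, class = "logLik")
}

#' @export
coef.gbmtm <- function(object, ...) object$beta

#' Posterior membership, modal class, or fitted trajectories
#'
#' @param object A fitted [gbmtm()] model.
#' @param newdata Optional matrix of standardized grids (defaults to the
#'   training posteriors for `type = "posterior"`/`"class"`).
#' @param type `"posterior"` (N x K membership probabilities), `"class"`
#'   (modal labels, ties to the lowest group index), or `"trajectory"`
#'   (fitted group-mean curves; a `K x V x horizon` array, in native channel
#'   units when the fit carries standardization parameters and
#'   `standardized = FALSE`).
#' @param standardized For `type = "trajectory"`: return curves on the
#'   Z-score scale instead of native units.
#' @param ... Unused.
#' @export
predict.gbmtm <- function(object, newdata = NULL,
                          type = c("posterior", "class", "trajectory"),
                          standardized = FALSE, ...) {
  type <- match.arg(type)
  if (type == "trajectory") {
    X <- time_design(object$horizon, 3L)
    out <- array(NA_real_, c(object$K, object$V, object$horizon),
                 dimnames = list(NULL, dimnames(object$beta)[[2]], NULL))
    for (g in seq_len(object$K)) for (v in seq_len(object$V)) {
      b <- object$beta[g, v, ]
      b[is.na(b)] <- 0
      cur <- as.numeric(X %*% b)
      if (!standardized && !is.null(object$scaling))
        cur <- cur * object$scaling$sd[v] + object$scaling$mean[v]
      out[g, v, ] <- cur
    }
    return(out)
  }
  W <- if (is.null(newdata)) object$W else {
    if (inherits(newdata, "vital_grids")) newdata <- newdata$z
    pars <- list(pi = object$pi,
                 mu = traj_mu_matrix(object),
                 sigma_cell = sigma_cell_matrix(object))
    estep(unclass(newdata), pars, object$horizon, object$V, object$K)$W
  }
  if (type == "posterior") W else max.col(W, ties.method = "first")
}

traj_mu_matrix <- function(object) {
  X <- time_design(object$horizon, 3L)
  mu <- matrix(NA_real_, object$K, object$V * object$horizon)
  for (g in seq_len(object$K)) for (v in seq_len(object$V)) {
    b <- object$beta[g, v, ]; b[is.na(b)] <- 0
    mu[g, (v - 1L) * object$horizon + seq_len(object$horizon)] <-
      as.numeric(X %*% b)
  }
  mu
}

sigma_cell_matrix <- function(object) {
  t(apply(object$sigma, 1, function(s) rep(s, each = object$horizon)))
}

#' Residuals under the modal group assignment
#'
#' Standardized-scale residuals `y_ivt - mu_{g(i), v, t}` with `g(i)` the
#' modal group of subject `i`.
#'
#' @param object A fitted `gbmtm` model.
#' @param ... Unused.
#' @export
residuals.gbmtm <- function(object, ...) {
  object$data - traj_mu_matrix(object)[object$labels, , drop = FALSE]
}

#' @export
summary.gbmtm <- function(object, ...) {
  d <- gbmtm_diagnostics(object)
  structure(list(fit = object, diagnostics = d), class = "summary.gbmtm")
}

#' @export
print.summary.gbmtm <- function(x, ...) {
  print(x$fit)
  d <- x$diagnostics
  cat(sprintf("  relative entropy %.3f\n", d$entropy))
  tab <- data.frame(group = seq_len(x$fit$K),
                    share = round(d$shares, 4),
                    AvePP = round(d$avepp, 3),
                    OCC = round(d$occ, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot fitted group-mean trajectories
#'
#' One panel per channel; curves in native units when standardization
#' parameters are attached to the fit.
#'
#' @param x A fitted `gbmtm` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gbmtm <- function(x, ...) {
  tr <- predict(x, type = "trajectory")
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  hrs <- 0:(x$horizon - 1)
  for (v in seq_len(x$V)) {
    graphics::matplot(hrs, t(tr[, v, ]), type = "l", lty = 1, lwd = 2,
                      xlab = "hour since admission", ylab = VITAL_CHANNELS[v],
                      main = VITAL_CHANNELS[v], ...)
  }
  invisible(x)
}

#' Simulate grids from a fitted multi-trajectory model
#'
#' Draws group labels from the fitted mixing proportions and cell values from
#' the fitted per-(group, channel) normal model; returns standardized-scale
#' grids comparable to the training input.
#'
#' @param object A fitted `gbmtm` model.
#' @param nsim Number of subjects to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @export
simulate.gbmtm <- function(object, nsim = object$N, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- traj_mu_matrix(object)
  sc <- sigma_cell_matrix(object)
  g <- sample.int(object$K, nsim, replace = TRUE, prob = object$pi)
  Y <- mu[g, , drop = FALSE] +
    matrix(stats::rnorm(nsim * ncol(mu)), nsim) * sc[g, , drop = FALSE]
  structure(Y, horizon = object$horizon, group = g,
            class = c("hourly_grids", "matrix"))
}
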