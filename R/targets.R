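## Safe-zone extraction: per-parameter random-forest mortality models within
## the high-risk cluster, univariate partial dependence over the blood gas
## grid, and the lowest-predicted-risk interval.

#' Random-forest risk model specification
#'
#' Tuning grid and cross-validation settings for [train_risk_model()].
#' Defaults: trees in {200, 500}, per-split features in {sqrt(p), p/3},
#' minimum node size in {5, 20}, five folds, AUROC as the criterion.
#'
#' @param trees Candidate forest sizes.
#' @param mtry Candidate per-split feature counts (`NULL` = sqrt(p) and p/3).
#' @param min_node Candidate minimum node sizes.
#' @param folds Cross-validation folds (>= 2).
#' @param seed Seed for fold assignment and tree growth.
#' @return List of class `risk_model_spec`.
#' @export
risk_model_spec <- function(trees = c(200L, 500L), mtry = NULL,
                            min_node = c(5L, 20L), folds = 5L, seed = 1L) {
  if (folds < 2L) stop_input("folds must be >= 2")
  if (!length(trees) || !length(min_node)) stop_input("tuning grid is empty")
  structure(list(trees = as.integer(trees), mtry = mtry,
                 min_node = as.integer(min_node), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "risk_model_spec")
}

#' Train a per-parameter random-forest ICU-mortality model
#'
#' Fits one probability forest for a single blood gas parameter, with
#' clinical covariates plus that parameter as features, choosing
#' hyperparameters by seeded k-fold cross-validation maximizing the area
#' under the ROC curve of pooled out-of-fold predictions.
#'
#' @param data Records of the modeled cluster, with `icu_event` and features.
#' @param param Blood gas column included as the feature of interest.
#' @param covars Clinical covariate columns.
#' @param spec A [risk_model_spec()].
#' @return Object of class `risk_model`: the final `ranger` forest, the CV
#'   `report` (one row per grid point with its AUROC), chosen parameters,
#'   and the training features (used as the partial-dependence background).
#' @export
train_risk_model <- function(data, param,
                             covars = c("age", "sex", "sofa", "apsiii",
                                        "vent", "crrt", "rrt"),
                             spec = risk_model_spec()) {
  if (nrow(data) < 50L) stop_input("need at least 50 records")
  y <- data$icu_event
  if (is.null(y)) stop_input("data lacks `icu_event`")
  if (sum(y) < 5L) stop_input("need at least 5 events")
  if (length(unique(y)) < 2L) stop_input("outcome has a single class")
  feats <- c(covars, param)
  miss <- setdiff(feats, names(data))
  if (length(miss)) stop_input("missing feature(s): ", paste(miss, collapse = ", "))
  X <- data[feats]
  p <- ncol(X)
  mtry_cand <- spec$mtry %||% unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3))))
  grid <- expand.grid(trees = spec$trees, mtry = mtry_cand,
                      min_node = spec$min_node)
  yf <- factor(y, levels = c(0, 1))

  set.seed(spec$seed)
  fold <- sample(rep(seq_len(spec$folds), length.out = nrow(X)))
  auc <- numeric(nrow(grid))
  for (j in seq_len(nrow(grid))) {
    pred <- numeric(nrow(X))
    for (f in seq_len(spec$folds)) {
      tr <- fold != f
      rf <- ranger::ranger(x = X[tr, , drop = FALSE], y = yf[tr],
                           probability = TRUE,
                           num.trees = grid$trees[j], mtry = grid$mtry[j],
                           min.node.size = grid$min_node[j],
                           seed = spec$seed + f, num.threads = 1)
      pred[!tr] <- predict(rf, data = X[!tr, , drop = FALSE],
                           num.threads = 1)$predictions[, "1"]
    }
    auc[j] <- as.numeric(pROC::auc(pROC::roc(y, pred, quiet = TRUE,
                                             direction = "<", levels = c(0, 1))))
  }
  best <- which.max(auc)            # ties: first (deterministic) grid row
  final <- ranger::ranger(x = X, y = yf, probability = TRUE,
                          num.trees = grid$trees[best], mtry = grid$mtry[best],
                          min.node.size = grid$min_node[best],
                          seed = spec$seed, num.threads = 1)
  structure(list(model = final, param = param, covars = covars,
                 features = X, y = y,
                 report = cbind(grid, auroc = auc),
                 chosen = grid[best, ], cv_auroc = auc[best], spec = spec),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Random-forest ICU-mortality model for %s (n = %d, events = %d)\n",
              x$param, nrow(x$features), sum(x$y)))
  cat(sprintf("  chosen: %d trees, mtry %d, min node %d; CV AUROC %.3f\n",
              x$chosen$trees, x$chosen$mtry, x$chosen$min_node, x$cv_auroc))
  invisible(x)
}

# Predicted death probability for arbitrary feature rows.
predict_risk <- function(model, newdata) {
  predict(model$model, data = newdata, num.threads = 1)$predictions[, "1"]
}

#' Univariate partial dependence of predicted ICU mortality
#'
#' `PD(x) = (1/N) sum_i f(x, z_i)`: the mean predicted death probability when
#' the parameter is forced to `x` and the other features keep their observed
#' values. The default grid spans the within-sample 1st-99th percentiles in
#' 50 points.
#'
#' @param model A [train_risk_model()] fit, or any object usable with
#'   `predict_fun`.
#' @param grid Evaluation grid (strictly increasing; default as above).
#' @param n_grid Grid size when `grid` is NULL.
#' @param data Background feature rows (default: the training features).
#' @param param Column forced over the grid (default: the model's parameter).
#' @param predict_fun Function `(model, newdata) -> probabilities`; defaults
#'   to the forest's probability predictions.
#' @return Object of class `pd_profile`: data frame `x`, `pd` with attributes
#'   `param` and `n`.
#' @export
partial_dependence <- function(model, grid = NULL, n_grid = 50L,
                               data = NULL, param = NULL,
                               predict_fun = NULL) {
  if (inherits(model, "risk_model")) {
    data <- data %||% model$features
    param <- param %||% model$param
    predict_fun <- predict_fun %||% predict_risk
  }
  if (is.null(data) || is.null(param) || is.null(predict_fun))
    stop_input("`data`, `param` and `predict_fun` are required for custom models")
  if (is.null(grid)) {
    qs <- stats::quantile(data[[param]], c(0.01, 0.99), names = FALSE)
    grid <- seq(qs[1], qs[2], length.out = n_grid)
  }
  if (is.unsorted(grid, strictly = TRUE))
    stop_input("grid must be strictly increasing")
  rng <- range(data[[param]])
  if (min(grid) < rng[1] || max(grid) > rng[2])
    warning("grid extends outside the observed support of ", param)
  n <- nrow(data)
  nd <- data[rep(seq_len(n), length(grid)), , drop = FALSE]
  nd[[param]] <- rep(grid, each = n)
  pr <- predict_fun(model, nd)
  pd <- as.numeric(rowsum(pr, rep(seq_along(grid), each = n))) / n
  structure(data.frame(x = grid, pd = pd),
            param = param, n = n, class = c("pd_profile", "data.frame"))
}

#' Bivariate partial dependence surface
#'
#' The two-feature analogue of [partial_dependence()], used for
#' visualization: `PD(x, y)` averages predictions with both features forced.
#'
#' @param model A [train_risk_model()] fit (or custom, see
#'   [partial_dependence()]).
#' @param params Character vector of the two features.
#' @param grids List of two grids (default 25-point 1st-99th percentile
#'   spans).
#' @inheritParams partial_dependence
#' @return List of class `pd_surface`: `x`, `y`, and matrix `z`
#'   (`length(x)` rows by `length(y)` columns).
#' @export
pd_surface <- function(model, params, grids = NULL, data = NULL,
                       predict_fun = NULL) {
  if (inherits(model, "risk_model")) {
    data <- data %||% model$features
    predict_fun <- predict_fun %||% predict_risk
  }
  stopifnot(length(params) == 2L, all(params %in% names(data)))
  if (is.null(grids))
    grids <- lapply(params, function(p) {
      qs <- stats::quantile(data[[p]], c(0.01, 0.99), names = FALSE)
      seq(qs[1], qs[2], length.out = 25L)
    })
  n <- nrow(data)
  z <- matrix(NA_real_, length(grids[[1]]), length(grids[[2]]))
  for (j in seq_along(grids[[2]])) {
    nd <- data[rep(seq_len(n), length(grids[[1]])), , drop = FALSE]
    nd[[params[1]]] <- rep(grids[[1]], each = n)
    nd[[params[2]]] <- grids[[2]][j]
    pr <- predict_fun(model, nd)
    z[, j] <- as.numeric(rowsum(pr, rep(seq_along(grids[[1]]), each = n))) / n
  }
  structure(list(x = grids[[1]], y = grids[[2]], z = z, params = params),
            class = "pd_surface")
}

#' Extract the lowest-risk ("safe zone") interval from a PD profile
#'
#' With threshold `tau = PDmin + delta * (PDmax - PDmin)`, the safe zone is
#' the maximal contiguous grid run containing the global PD minimizer
#' (leftmost on ties) on which `PD <= tau`. Endpoints are reported at grid
#' resolution. A flat profile yields the full grid span with a warning.
#'
#' @param profile A [partial_dependence()] result (>= 3 grid points).
#' @param delta Fraction of the PD range defining "lowest risk".
#' @return Object of class `safe_zone`: `param`, `lo`, `hi`, `delta`,
#'   `pd_at_lo`, `pd_at_hi`, `pd_min`, `pd_max`.
#' @export
extract_safe_zone <- function(profile, delta = 0.2) {
  x <- profile$x; pd <- profile$pd
  if (length(x) < 3L) stop_input("PD profile needs at least 3 grid points")
  pd_min <- min(pd); pd_max <- max(pd)
  if (pd_max - pd_min <= 0) {
    warning("flat PD profile; safe zone spans the whole grid")
    i_lo <- 1L; i_hi <- length(x)
  } else {
    tau <- pd_min + delta * (pd_max - pd_min)
    m <- which.min(pd)                      # leftmost global minimizer
    ok <- pd <= tau + 1e-15
    i_lo <- m; while (i_lo > 1L && ok[i_lo - 1L]) i_lo <- i_lo - 1L
    i_hi <- m; while (i_hi < length(x) && ok[i_hi + 1L]) i_hi <- i_hi + 1L
  }
  structure(list(param = attr(profile, "param"), lo = x[i_lo], hi = x[i_hi],
                 delta = delta, pd_at_lo = pd[i_lo], pd_at_hi = pd[i_hi],
                 pd_min = pd_min, pd_max = pd_max,
                 minimizer = x[which.min(pd)], n = attr(profile, "n")),
            class = "safe_zone")
}

#' @export
format.safe_zone <- function(x, digits = 2, ...) {
  paste(x$param, format_range(x$lo, x$hi, digits))
}

#' @export
print.safe_zone <- function(x, ...) {
  cat("Safe zone:", format(x), sprintf("(delta = %.2f)\n", x$delta))
  invisible(x)
}

#' Tabulate safe zones across blood gas parameters
#'
#' @param zones Named list of [extract_safe_zone()] results.
#' @param units Optional named character vector of units per parameter.
#' @return Data frame `param`, `lo`, `hi`, `units`, `delta`, `pd_min`,
#'   `pd_max`, `n`.
#' @export
safe_zone_report <- function(zones, units = NULL) {
  do.call(rbind, lapply(zones, function(z)
    data.frame(param = z$param, lo = z$lo, hi = z$hi,
               units = if (is.null(units)) "" else units[[z$param]] %||% "",
               delta = z$delta, pd_min = z$pd_min, pd_max = z$pd_max,
               n = z$n %||% NA_integer_,
               row.names = NULL, stringsAsFactors = FALSE)))
}

#' Jaccard overlap of two intervals
#'
#' Intersection length over union length; the agreement measure used to
#' validate extracted safe zones against the generator's risk-minimizing
#' intervals.
#'
#' @param a,b First interval endpoints (`a <= b`).
#' @param c,d Second interval endpoints (`c <= d`).
#' @return Scalar in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b, c, d) {
  inter <- max(0, min(b, d) - max(a, c))
  uni <- max(b, d) - min(a, c)
  if (uni <= 0) return(as.numeric(inter == 0))
  inter / uni
}
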