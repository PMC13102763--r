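# Random-forest risk models, partial dependence, safe-zone extraction.

test_that("cross-validated AUROC is near chance for pure-noise labels", {
  aucs <- sapply(1:3, function(s) {
    set.seed(s)
    n <- 600
    d <- data.frame(age = rnorm(n, 65, 10), sex = rbinom(n, 1, 0.5),
                    sofa = rnorm(n, 6, 2), apsiii = rnorm(n, 50, 15),
                    vent = rbinom(n, 1, 0.5), crrt = rbinom(n, 1, 0.2),
                    rrt = rbinom(n, 1, 0.2), ph = rnorm(n, 7.4, 0.08),
                    icu_event = rbinom(n, 1, 0.3))
    train_risk_model(d, "ph",
                     spec = risk_model_spec(trees = 200, min_node = 10,
                                            seed = s))$cv_auroc
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("a deterministic threshold outcome is almost perfectly discriminated", {
  set.seed(2)
  n <- 400
  d <- data.frame(age = rnorm(n, 65, 10), sex = rbinom(n, 1, 0.5),
                  sofa = rnorm(n, 6, 2), apsiii = rnorm(n, 50, 15),
                  vent = rbinom(n, 1, 0.5), crrt = rbinom(n, 1, 0.2),
                  rrt = rbinom(n, 1, 0.2), lactate = rnorm(n, 2.5, 1.5))
  d$icu_event <- as.integer(d$lactate > 3)
  rm <- train_risk_model(d, "lactate",
                         spec = risk_model_spec(trees = 200, min_node = 5,
                                                seed = 2))
  expect_gte(rm$cv_auroc, 0.95)
})

test_that("training is deterministic under a fixed seed", {
  lc <- labeled_cohort(600, seed = 4)
  hr <- lc$data[lc$data$cluster == 2, ]
  spec <- risk_model_spec(trees = c(100, 200), min_node = c(5, 20), seed = 7)
  m1 <- train_risk_model(hr, "ph", spec = spec)
  m2 <- train_risk_model(hr, "ph", spec = spec)
  expect_identical(m1$chosen, m2$chosen)
  expect_identical(predict_rf <- trajtargets:::predict_risk(m1, m1$features),
                   trajtargets:::predict_risk(m2, m2$features))
  p1 <- partial_dependence(m1); p2 <- partial_dependence(m2)
  expect_identical(p1$pd, p2$pd)
})

test_that("input contracts are enforced", {
  lc <- labeled_cohort(300, seed = 5)
  hr <- lc$data[lc$data$cluster == 2, ]
  expect_error(train_risk_model(hr[1:20, ], "ph"), "50")
  ok <- hr; ok$icu_event <- 0L
  expect_error(train_risk_model(ok, "ph"), "5 events")
  expect_error(train_risk_model(hr, "not_a_column"), "missing feature")
  expect_error(risk_model_spec(folds = 1), "folds")
  expect_error(risk_model_spec(trees = integer()), "grid")
})

test_that("partial dependence reduces to known closed forms", {
  d <- data.frame(gas = seq(0, 10, length.out = 40), z = rnorm(40))
  grid <- seq(1, 9, length.out = 17)
  # constant model
  pd_const <- partial_dependence(NULL, grid = grid, data = d, param = "gas",
                                 predict_fun = function(m, nd) rep(0.37, nrow(nd)))
  expect_equal(pd_const$pd, rep(0.37, 17))
  # single stump on the parameter: step function with the leaf values
  stump <- function(m, nd) ifelse(nd$gas <= 4.2, 0.1, 0.6)
  pd_stump <- partial_dependence(NULL, grid = grid, data = d, param = "gas",
                                 predict_fun = stump)
  expect_equal(pd_stump$pd, ifelse(grid <= 4.2, 0.1, 0.6))
  # model ignoring the parameter: constant at the mean prediction
  other <- function(m, nd) plogis(nd$z)
  pd_other <- partial_dependence(NULL, grid = grid, data = d, param = "gas",
                                 predict_fun = other)
  expect_equal(pd_other$pd, rep(mean(plogis(d$z)), 17), tolerance = 1e-12)
})

test_that("bivariate PD surfaces are additive for additive models and marginalize back", {
  set.seed(6)
  d <- data.frame(u = runif(30), v = runif(30), z = rnorm(30))
  f <- function(m, nd) 0.2 + 0.3 * nd$u + 0.1 * nd$v^2
  gx <- seq(0.1, 0.9, length.out = 11)
  gy <- seq(0.2, 0.8, length.out = 9)
  surf <- pd_surface(NULL, c("u", "v"), grids = list(gx, gy), data = d,
                     predict_fun = f)
  pdx <- partial_dependence(NULL, grid = gx, data = d, param = "u",
                            predict_fun = f)
  pdy <- partial_dependence(NULL, grid = gy, data = d, param = "v",
                            predict_fun = f)
  add <- outer(pdx$pd, pdy$pd, `+`) - mean(f(NULL, d))
  expect_equal(surf$z, add, tolerance = 1e-10)
  # marginalizing the surface over the data distribution of v reproduces PD(u)
  surf2 <- pd_surface(NULL, c("u", "v"), grids = list(gx, d$v), data = d,
                      predict_fun = f)
  expect_equal(rowMeans(surf2$z), pdx$pd, tolerance = 1e-10)
})

test_that("safe-zone extraction honors its threshold geometry", {
  # V-shaped profile, delta = 0: the zone collapses onto the minimizer
  prof <- structure(data.frame(x = 1:11, pd = abs(1:11 - 7) / 10 + 0.1),
                    param = "gas", n = 100L,
                    class = c("pd_profile", "data.frame"))
  z0 <- extract_safe_zone(prof, delta = 0)
  expect_equal(c(z0$lo, z0$hi), c(7, 7))
  # monotone decreasing profile: zone abuts the upper grid bound
  prof2 <- structure(data.frame(x = 1:11, pd = seq(0.9, 0.1, length.out = 11)),
                     param = "gas", n = 100L,
                     class = c("pd_profile", "data.frame"))
  z2 <- extract_safe_zone(prof2, delta = 0.2)
  expect_equal(z2$hi, 11)
  # flat profile: full span with warning
  prof3 <- structure(data.frame(x = 1:5, pd = rep(0.2, 5)),
                     param = "gas", n = 10L,
                     class = c("pd_profile", "data.frame"))
  expect_warning(z3 <- extract_safe_zone(prof3), "flat")
  expect_equal(c(z3$lo, z3$hi), c(1, 5))
  # zone always contains the minimizer and widens monotonically with delta
  set.seed(8)
  for (i in 1:20) {
    prof4 <- structure(data.frame(x = 1:31, pd = runif(31)),
                       param = "gas", n = 10L,
                       class = c("pd_profile", "data.frame"))
    widths <- sapply(c(0, 0.1, 0.2, 0.4, 0.8), function(dl) {
      z <- extract_safe_zone(prof4, delta = dl)
      expect_lte(z$lo, z$minimizer); expect_gte(z$hi, z$minimizer)
      z$hi - z$lo
    })
    expect_true(all(diff(widths) >= 0))
  }
})

test_that("safe zones print in the clinical interval style", {
  z <- structure(list(param = "pH", lo = 7.32, hi = 7.64, delta = 0.2,
                      pd_at_lo = 0.2, pd_at_hi = 0.2, pd_min = 0.1,
                      pd_max = 0.5, minimizer = 7.4, n = 100L),
                 class = "safe_zone")
  expect_equal(format(z), "pH 7.32–7.64")
})

test_that("the safe-zone report survives a round trip and re-extraction", {
  lc <- labeled_cohort(800, seed = 13)
  hr <- lc$data[lc$data$cluster == 2, ]
  spec <- risk_model_spec(trees = 150, min_node = 10, seed = 3)
  params <- c("ph", "lactate", "base_excess")
  zones <- list(); profs <- list()
  for (p in params) {
    m <- train_risk_model(hr, p, spec = spec)
    profs[[p]] <- partial_dependence(m)
    zones[[p]] <- extract_safe_zone(profs[[p]])
  }
  rep1 <- safe_zone_report(zones)
  expect_equal(nrow(rep1), length(params))
  # lossless file round trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rep1, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$lo, rep1$lo)
  expect_equal(back$hi, rep1$hi)
  # zones recomputed from persisted PD profiles match the report exactly
  pf <- tempfile(fileext = ".csv")
  utils::write.csv(do.call(rbind, lapply(names(profs), function(p)
    data.frame(param = p, x = profs[[p]]$x, pd = profs[[p]]$pd))),
    pf, row.names = FALSE)
  saved <- utils::read.csv(pf, stringsAsFactors = FALSE)
  for (p in params) {
    sp <- saved[saved$param == p, ]
    prof <- structure(data.frame(x = sp$x, pd = sp$pd), param = p,
                      n = attr(profs[[p]], "n"),
                      class = c("pd_profile", "data.frame"))
    z <- extract_safe_zone(prof)
    expect_equal(c(z$lo, z$hi),
                 c(rep1$lo[rep1$param == p], rep1$hi[rep1$param == p]))
  }
})
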