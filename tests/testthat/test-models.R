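test_that("least-squares fits match closed forms, with and without dummies", {
  set.seed(20)
  X <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("v1", "v2")))
  y_exact <- as.numeric(2 + 3 * X[, 1] - X[, 2])
  fit <- fit_olr(X, y_exact)
  expect_equal(fit$r2, 1)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(unname(fit$coef), c(2, 3, -1))

  # irrelevant features, exact group means: dummy coefficients are the means
  shade <- rep(c(0, 0.25, 0.5, 0.75), each = 8)
  mu <- c(18, 26, 32, 29)
  y_groups <- rep(mu, each = 8)
  Xn <- matrix(rnorm(32 * 2), 32, dimnames = list(NULL, c("v1", "v2")))
  fitd <- fit_olr(Xn, y_groups, shade = shade)
  expect_equal(unname(fitd$coef[paste0("shade", c(0, 0.25, 0.5, 0.75))]), mu)
  expect_equal(unname(fitd$coef[c("v1", "v2")]), c(0, 0))

  # 6-row design against a normal-equations hand solve
  X6 <- matrix(c(1, 2, 3, 4, 5, 6, 2, 1, 4, 3, 6, 5), 6,
               dimnames = list(NULL, c("p", "q")))
  y6 <- c(3, 1, 4, 1, 5, 9)
  D <- cbind(1, X6)
  expect_equal(unname(fit_olr(X6, y6)$coef),
               as.numeric(solve(crossprod(D), crossprod(D, y6))))

  Xdup <- cbind(a = X6[, 1], b = 2 * X6[, 1])
  expect_error(fit_olr(Xdup, y6), "rank-deficient.*b")
})

test_that("dummy variables never decrease in-sample fit (nested models)", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 60
    shade <- sample(rep(c(0, 0.25, 0.5, 0.75), each = n / 4))
    X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("v1", "v2")))
    y <- 20 + 2 * X[, 1] + 5 * shade + rnorm(n, 0, 2)
    expect_gte(fit_olr(X, y, shade = shade)$r2, fit_olr(X, y)$r2)
  }
})

test_that("REML mixed model matches lme4 on variance components and fixed effects", {
  skip_if_not_installed("lme4")
  set.seed(22)
  n <- 160
  g <- rep(letters[1:8], each = n / 8)
  u <- rnorm(8, 0, 2)
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("v1", "v2")))
  y <- as.numeric(10 + 1.5 * X[, 1] - 2 * X[, 2] + u[as.integer(factor(g))] +
                    rnorm(n, 0, 1.5))
  ours <- fit_lmm(X, g, y)
  ref <- lme4::lmer(y ~ v1 + v2 + (1 | g),
                    data = data.frame(y = y, v1 = X[, 1], v2 = X[, 2], g = g),
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(ours$sigma2_random, vc$vcov[1], tolerance = 1e-4)
  expect_equal(ours$sigma2_residual, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(ours$coef), unname(lme4::fixef(ref)), tolerance = 1e-5)
  # BLUP predictions for known groups
  expect_equal(unname(ours$blup),
               unname(lme4::ranef(ref)$g[, 1]), tolerance = 1e-4)
})

test_that("balanced no-covariate BLUPs equal the classic shrinkage formula", {
  set.seed(23)
  k <- 6; m <- 15
  g <- rep(seq_len(k), each = m)
  y <- 25 + rep(rnorm(k, 0, 3), each = m) + rnorm(k * m, 0, 2)
  fit <- fit_lmm(matrix(nrow = k * m, ncol = 0), g, y)
  shrink <- fit$sigma2_random / (fit$sigma2_random + fit$sigma2_residual / m)
  centered <- tapply(y, g, mean) - fit$coef[["(Intercept)"]]
  expect_equal(unname(fit$blup), as.numeric(shrink * centered), tolerance = 1e-6)
  # balanced GLS intercept is the grand mean
  expect_equal(fit$coef[["(Intercept)"]], mean(y), tolerance = 1e-8)
})

test_that("zero between-group variance degenerates the mixed model to OLS", {
  set.seed(24)
  n <- 400
  g <- rep(1:8, each = n / 8)
  X <- matrix(rnorm(n), n, dimnames = list(NULL, "v1"))
  y <- as.numeric(5 + 2 * X[, 1] + rnorm(n))   # no group effect in truth
  fit <- fit_lmm(X, g, y)
  ols <- fit_olr(X, y)
  expect_lt(fit$sigma2_random, 0.2)
  expect_equal(unname(fit$coef), unname(ols$coef), tolerance = 1e-2)
  expect_warning(fit_lmm(X, rep(1, n), y), "single group")
})

test_that("random forest honors its determinism and degenerate contracts", {
  set.seed(25)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
  y_const <- rep(7, 40)
  rf <- suppressWarnings(fit_rf(X, y_const, seed = 3, n_trees = 50))
  expect_equal(stats::predict(rf, X), rep(7, 40))

  y <- as.numeric(X %*% c(2, -1, 0.5) + rnorm(40, 0, 0.5))
  rf1 <- fit_rf(X, y, seed = 9, n_trees = 100)
  rf2 <- fit_rf(X, y, seed = 9, n_trees = 100)
  expect_identical(stats::predict(rf1, X), stats::predict(rf2, X))
  expect_error(fit_rf(X[1:5, ], y[1:5]), "at least 10")
})

test_that("random forest generalization does not exceed its training fit", {
  r2 <- t(vapply(1:8, function(s) {
    set.seed(200 + s)
    n <- 80
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- as.numeric(X %*% c(2, -1, 1) + rnorm(n))
    tr <- seq_len(60)
    rf <- fit_rf(X[tr, ], y[tr], seed = s, n_trees = 200)
    c(train = regression_metrics(y[tr] + 30, stats::predict(rf, X[tr, ]) + 30)["r2"],
      test = regression_metrics(y[-tr] + 30, stats::predict(rf, X[-tr, ]) + 30)["r2"])
  }, c(train = 0, test = 0)))
  expect_gt(mean(r2[, "train"]), mean(r2[, "test"]))
})

test_that("support vector regression tunes reproducibly and fits clean signal", {
  set.seed(26)
  X <- matrix(rnorm(60 * 2), 60, dimnames = list(NULL, c("a", "b")))
  y_const <- rep(30, 60)
  expect_error(fit_svr(X, y_const), "zero variance")

  y <- as.numeric(20 + 3 * X[, 1] - 2 * X[, 2])
  grids <- list(cost = 2^(0:6), gamma = 2^c(-4, -2, 0), eps = c(0.01, 0.1))
  tr <- seq_len(45)
  fit <- fit_svr(X[tr, ], y[tr], cost_grid = grids$cost,
                 gamma_grid = grids$gamma, epsilon_grid = grids$eps,
                 k_folds = 5, seed = 4)
  m <- regression_metrics(y[-tr], stats::predict(fit, X[-tr, ]))
  expect_gt(m["r2"], 0.95)

  fit2 <- fit_svr(X[tr, ], y[tr], cost_grid = grids$cost,
                  gamma_grid = grids$gamma, epsilon_grid = grids$eps,
                  k_folds = 5, seed = 4)
  expect_identical(fit$tuning, fit2$tuning)
})

test_that("fit reports carry both splits and print cleanly", {
  set.seed(27)
  n <- 60
  shade <- rep(c(0, 0.25, 0.5, 0.75), each = n / 4)
  X <- matrix(rnorm(n), n, dimnames = list(NULL, "v1"))
  y <- 20 + 10 * shade + 2 * X[, 1] + rnorm(n)
  tr <- sample(n, 45)
  fit <- fit_olr(X[tr, , drop = FALSE], y[tr], shade = shade[tr])
  rep <- model_report(fit,
                      train = list(X = X[tr, , drop = FALSE], y = y[tr],
                                   shade = shade[tr]),
                      test = list(X = X[-tr, , drop = FALSE], y = y[-tr],
                                  shade = shade[-tr]))
  expect_s3_class(rep, "model_fit_report")
  expect_true(all(is.finite(c(rep$train, rep$test))))
  expect_gte(rep$train["rmse"], 0)
  expect_output(print(rep), "OLR model")
})
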