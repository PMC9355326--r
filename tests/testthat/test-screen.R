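test_that("Pearson correlation and significance match the t reference and a permutation oracle", {
  x <- 1:10
  perfect <- pearson_with_p(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  set.seed(8)
  a <- rnorm(20); b <- 0.4 * a + rnorm(20)
  got <- pearson_with_p(a, b)
  r_obs <- abs(cor(a, b))
  perm <- mean(replicate(1e4, abs(cor(a, sample(b)))) >= r_obs)
  se <- sqrt(got$p * (1 - got$p) / 1e4)
  expect_lt(abs(perm - got$p), 4 * se + 1e-4)

  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "variance")
})

test_that("VIF matches its defining formula on constructed designs", {
  # mutually orthogonal centered columns -> all VIF exactly 1
  n <- 24
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)

  # auxiliary R^2 = 0.9 by construction -> VIF = 10 (band boundary)
  u <- Q[, 1] / sqrt(sum(Q[, 1]^2))
  v <- Q[, 2] / sqrt(sum(Q[, 2]^2))
  X <- cbind(x1 = u, x2 = sqrt(0.9) * u + sqrt(0.1) * v)
  expect_equal(unname(vif(X)), c(10, 10), tolerance = 1e-8)

  expect_error(vif(cbind(rnorm(10), rep(2, 10))), "constant")
  expect_equal(vif_class(c(3, 10, 15, 20, 25)),
               c("none", "some", "some", "some", "serious"))
})

test_that("the REVI/RERVI affine pair drives both VIFs to the cap", {
  set.seed(10)
  ch <- data.frame(nir = runif(40, .5, .9), re = runif(40, .2, .5),
                   red = runif(40, .05, .3))
  X <- cbind(REVI = ch$nir / ch$re - 1, RERVI = ch$nir / ch$re,
             NDVI = (ch$nir - ch$red) / (ch$nir + ch$red))
  v <- vif(X)
  expect_equal(unname(v["REVI"]), 1e6)
  expect_equal(unname(v["RERVI"]), 1e6)
  expect_lt(v["NDVI"], 10)
})

test_that("the significance pre-filter keeps signal and drops noise", {
  p <- c(a = 0.001, b = 0.01, c = 0.049)
  expect_equal(prefilter(p), c("a", "b", "c"))
  expect_error(prefilter(c(a = 0.2, b = 0.9)), "all features dropped")

  # designated noise columns fall out in most replicates; the theoretical
  # rate is (1 - alpha)^2 = 0.9025, so the bound allows Monte-Carlo error
  dropped_noise <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 60
    y <- rnorm(n, 25, 5)
    X <- cbind(s1 = y + rnorm(n, 0, 3), s2 = -y + rnorm(n, 0, 4),
               n1 = rnorm(n), n2 = rnorm(n))
    ps <- vapply(colnames(X), function(j) pearson_with_p(X[, j], y)$p, 0)
    surv <- suppressMessages(prefilter(ps))
    !("n1" %in% surv) && !("n2" %in% surv)
  }, TRUE)
  expect_gte(mean(dropped_noise), 0.85)
})

test_that("coordinate-descent lasso matches closed-form oracles", {
  set.seed(14)
  n <- 60; p <- 5
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- paste0("x", 1:p)
  beta_true <- c(2, -1, 0, 0.5, 0)
  y <- as.numeric(X %*% beta_true + rnorm(n, 0, 0.3))
  yc <- y - mean(y)

  # kill condition: lambda at or above max_j |2 x_j' y| zeroes everything
  lmax <- max(abs(2 * crossprod(X, yc)))
  expect_true(all(lasso_cd(X, yc, lmax)$beta == 0))
  expect_true(all(lasso_cd(X, yc, lmax * 1.5)$beta == 0))

  # lambda = 0 recovers the normal-equations OLS solution
  ols <- solve(crossprod(X), crossprod(X, yc))
  expect_equal(unname(lasso_cd(X, yc, 0)$beta), as.numeric(ols),
               tolerance = 1e-6)

  # univariate closed form over a ladder of penalties
  x1 <- X[, 1, drop = FALSE]
  for (lam in seq(0, 2 * max(abs(2 * crossprod(x1, yc))), length.out = 20)) {
    hand <- sign(sum(x1 * yc)) *
      max(abs(sum(x1 * yc)) - lam / 2, 0) / sum(x1^2)
    expect_equal(unname(lasso_cd(x1, yc, lam)$beta), hand, tolerance = 1e-10)
  }
})

test_that("lasso solutions satisfy the KKT conditions and match glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(15)
  n <- 80; p <- 8
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- paste0("x", 1:p)
  y <- as.numeric(X %*% c(3, -2, 1, rep(0, 5)) + rnorm(n))
  yc <- y - mean(y)
  for (lam in c(1, 10, 40, 120)) {
    fit <- lasso_cd(X, yc, lam)
    g <- 2 * crossprod(X, yc - X %*% fit$beta)
    act <- fit$beta != 0
    if (any(act)) expect_lt(max(abs(g[act] - lam * sign(fit$beta[act]))), 1e-5)
    if (any(!act)) expect_lt(max(abs(g[!act])) - lam, 1e-5)
    gn <- glmnet::glmnet(X, yc, lambda = lam / (2 * n), standardize = FALSE,
                         intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(fit$beta), as.numeric(gn$beta), tolerance = 1e-4)
  }
})

test_that("penalty selection by cross-validation retains a sparse, decorrelated set", {
  set.seed(16)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  X <- cbind(a = x1, b = x2, c = x3,
             alias = 3 * x1 - 2,        # planted exact collinear pair with a
             noise = rnorm(n))
  y <- 20 + 1.5 * x1 - 2 * x2 + 0.8 * x3 + rnorm(n)
  rep <- suppressMessages(lasso_select(X, y, seed = 6))
  expect_identical(rep$aliased, "alias")
  expect_true(all(c("a", "b", "c") %in% rep$retained))
  expect_false("alias" %in% rep$retained)
  expect_lt(rep$kkt_violation, 1e-5)
  if (length(rep$retained) > 1) {
    expect_true(all(vif(X[, rep$retained, drop = FALSE]) < 10))
  }
  # in-sample multiple R dominates the best retained univariate correlation
  best_single <- max(vapply(rep$retained,
                            function(j) abs(cor(X[, j], y)), 0))
  expect_gte(rep$multiple_r, best_single)
  # same seed, same report
  rep2 <- suppressMessages(lasso_select(X, y, seed = 6))
  expect_equal(rep$lambda_star, rep2$lambda_star)
  expect_equal(rep$beta, rep2$beta)
})

test_that("the full screening stage composes filter, VIF and lasso", {
  bm <- simulate_band_means(shade_config(n_per_level = 10), seed = 44)
  ft <- features_from_band_means(bm)
  scr <- suppressMessages(
    screen_features(ft[index_names()$ms], ft$spad_measured, seed = 2,
                    k_folds = 4))
  expect_s3_class(scr, "screen_report")
  expect_true(all(scr$retained %in% scr$prefiltered))
  expect_true(all(abs(scr$stats$r) <= 1))
  expect_true(all(scr$stats$vif >= 1 | scr$stats$vif == 1e6))
  out <- write_screen_report(scr, tempdir(), prefix = "scrtest")
  expect_true(all(file.exists(out)))
})
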