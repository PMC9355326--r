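#' One-hot shade dummy variables
#'
#' Encodes shade level membership as 0/1 columns, one per level, with no
#' separate global intercept, so each dummy coefficient is directly the
#' level intercept. Every row's dummies sum to 1.
#'
#' @param shade vector of shade fractions (or any categorical labels).
#' @param levels optional fixed level set (needed to encode test rows with
#'   the training coding).
#' @return n x k 0/1 matrix with columns `shade<level>`.
#' @export
shade_dummies <- function(shade, levels = NULL) {
  f <- factor(shade, levels = levels %||% sort(unique(shade)))
  if (anyNA(f)) stop("shade_dummies: shade value outside the coded levels", call. = FALSE)
  Z <- stats::model.matrix(~ 0 + f)
  colnames(Z) <- paste0("shade", gsub("^f", "", colnames(Z)))
  Z
}

# Build the regression design for the (dummy-)OLS model. Without dummies an
# intercept column is included; with dummies the one-hot block replaces it.
olr_design <- function(X, shade = NULL, levels = NULL) {
  X <- as.matrix(X)
  if (is.null(shade)) {
    D <- cbind(`(Intercept)` = 1, X)
  } else {
    D <- cbind(shade_dummies(shade, levels), X)
  }
  D
}

#' Ordinary least squares SPAD model, optionally with shade dummies
#'
#' Fits `SPAD = b x + sum_i a_i z_i + e` by least squares (QR). Without
#' shade, an ordinary intercept replaces the dummy block. The dummy
#' coefficients `a_i` are interpretable as shade-level intercepts.
#'
#' @param X matrix/data frame of selected index values.
#' @param y SPAD response.
#' @param shade optional shade level per row; when given, one-hot dummies
#'   (no global intercept) enter the design.
#' @return an object of class `spad_olr` with elements `coef`, `fitted`,
#'   `residuals`, `r2`, `features`, `shade_levels`.
#' @export
fit_olr <- function(X, y, shade = NULL) {
  X <- as.matrix(X)
  levels <- if (!is.null(shade)) sort(unique(shade))
  D <- olr_design(X, shade, levels)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) {
    bad <- colnames(D)[qr_d$pivot[(qr_d$rank + 1L):ncol(D)]]
    stop("fit_olr: rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_d, y)
  fitted <- as.numeric(D %*% beta)
  res <- y - fitted
  structure(list(coef = beta, fitted = fitted, residuals = res,
                 r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
                 features = colnames(X), shade_levels = levels),
            class = "spad_olr")
}

#' @export
predict.spad_olr <- function(object, X, shade = NULL, ...) {
  D <- olr_design(as.matrix(X)[, object$features, drop = FALSE],
                  shade, object$shade_levels)
  as.numeric(D %*% object$coef[colnames(D)])
}

#' Linear mixed model with random shade intercepts, fitted by REML
#'
#' Fits `SPAD = b x + c tau + e` where `tau` groups observations by shade
#' level and the level effects are random intercepts:
#' `y = F b + Z u + e`, `u ~ N(0, sigma2_r I)`, `e ~ N(0, sigma2_e I)`.
#' The variance ratio `theta = sigma2_r / sigma2_e` is profiled out of the
#' restricted log-likelihood and maximized by bounded one-dimensional golden
#' search on the log scale (tolerance 1e-8); the boundary `theta = 0` is
#' checked explicitly. Predictions for known groups use the BLUPs
#' `u_hat = theta Z' V^{-1} (y - F b_hat)`.
#'
#' @param X matrix/data frame of selected index values (the fixed effects).
#' @param groups shade level per row (>= 2 groups of >= 2 rows each; with a
#'   single group the model degenerates to [fit_olr()] with a warning).
#' @param y SPAD response.
#' @return an object of class `spad_lmm` with `coef`, `sigma2_random`,
#'   `sigma2_residual`, `blup`, `fitted`, `r2`, `theta`.
#' @export
fit_lmm <- function(X, groups, y) {
  X <- as.matrix(X)
  f <- factor(groups)
  if (nlevels(f) < 2L) {
    warning("fit_lmm: a single group carries no random effect; fitting OLR")
    return(fit_olr(X, y))
  }
  if (any(table(f) < 2L)) stop("fit_lmm: every group needs >= 2 records", call. = FALSE)
  Fm <- cbind(`(Intercept)` = 1, X)
  Z <- stats::model.matrix(~ 0 + f)
  n <- length(y); p <- ncol(Fm)

  neg_reml <- function(theta) {
    V <- diag(n) + theta * tcrossprod(Z)
    cV <- chol(V)
    Vi_F <- backsolve(cV, forwardsolve(t(cV), Fm))
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    FtViF <- crossprod(Fm, Vi_F)
    b <- solve(FtViF, crossprod(Fm, Vi_y))
    r <- y - Fm %*% b
    Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
    s2 <- sum(r * Vi_r) / (n - p)
    ld_V <- 2 * sum(log(diag(cV)))
    ld_F <- determinant(FtViF, logarithm = TRUE)$modulus
    0.5 * (ld_V + as.numeric(ld_F) + (n - p) * log(s2))
  }
  opt <- stats::optimize(function(lt) neg_reml(exp(lt)),
                         interval = c(log(1e-8), log(1e4)), tol = 1e-8)
  theta <- exp(opt$minimum)
  if (neg_reml(0) <= opt$objective) theta <- 0

  V <- diag(n) + theta * tcrossprod(Z)
  cV <- chol(V)
  Vi_F <- backsolve(cV, forwardsolve(t(cV), Fm))
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  b <- solve(crossprod(Fm, Vi_F), crossprod(Fm, Vi_y))
  r <- as.numeric(y - Fm %*% b)
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  s2e <- sum(r * Vi_r) / (n - p)
  u <- as.numeric(theta * crossprod(Z, Vi_r))
  names(u) <- levels(f)
  fitted <- as.numeric(Fm %*% b) + u[as.character(f)]
  structure(list(coef = stats::setNames(as.numeric(b), colnames(Fm)),
                 sigma2_random = theta * s2e, sigma2_residual = s2e,
                 blup = u, theta = theta, fitted = fitted,
                 r2 = 1 - sum((y - fitted)^2) / sum((y - mean(y))^2),
                 features = colnames(X)),
            class = "spad_lmm")
}

#' @export
predict.spad_lmm <- function(object, X, shade = NULL, ...) {
  Fm <- cbind(1, as.matrix(X)[, object$features, drop = FALSE])
  out <- as.numeric(Fm %*% object$coef)
  if (!is.null(shade)) {
    u <- object$blup[as.character(shade)]
    u[is.na(u)] <- 0  # unknown group: fixed part only
    out <- out + u
  }
  out
}

#' Random forest SPAD model
#'
#' Bootstrap-aggregated regression trees; the prediction is the mean over
#' trees. Defaults: 500 trees, `ceiling(p/3)` candidate features per split,
#' minimum node size 2, unlimited depth. Deterministic for a fixed seed.
#'
#' @param X matrix/data frame of index values.
#' @param y SPAD response.
#' @param shade optional shade level per row, entered as one-hot dummies.
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @param node_size minimum terminal node size.
#' @return an object of class `spad_rf`.
#' @export
fit_rf <- function(X, y, shade = NULL, n_trees = 500L, seed = 1L, node_size = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("fit_rf: need at least 10 rows", call. = FALSE)
  levels <- if (!is.null(shade)) sort(unique(shade))
  D <- if (is.null(shade)) X else cbind(X, shade_dummies(shade, levels))
  rf <- with_seed(seed, randomForest::randomForest(
    x = D, y = y, ntree = n_trees,
    mtry = max(1L, ceiling(ncol(D) / 3)), nodesize = node_size))
  structure(list(rf = rf, features = colnames(X), shade_levels = levels,
                 fitted = as.numeric(stats::predict(rf, D)),
                 n_trees = n_trees, seed = seed),
            class = "spad_rf")
}

#' @export
predict.spad_rf <- function(object, X, shade = NULL, ...) {
  X <- as.matrix(X)[, object$features, drop = FALSE]
  D <- if (is.null(object$shade_levels)) X
       else cbind(X, shade_dummies(shade, object$shade_levels))
  as.numeric(stats::predict(object$rf, D))
}

#' RBF support vector regression with cross-validated hyperparameters
#'
#' Epsilon-SVR with a radial basis function kernel. The triple
#' `(cost, gamma, epsilon)` is chosen by seeded k-fold cross-validation
#' minimizing MSE over log-spaced grids (defaults: cost `2^(-3..10)`,
#' gamma `2^(-10..3)`, epsilon `{0.01, 0.1, 0.5, 1}`); ties break to the
#' first grid point. Features are standardized internally by the solver.
#'
#' @param X matrix/data frame of index values.
#' @param y SPAD response (must have nonzero variance).
#' @param shade optional shade level per row, entered as one-hot dummies.
#' @param cost_grid,gamma_grid,epsilon_grid hyperparameter grids.
#' @param k_folds cross-validation folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return an object of class `spad_svr` with the chosen hyperparameters in
#'   `$tuning`.
#' @export
fit_svr <- function(X, y, shade = NULL,
                    cost_grid = 2^(-3:10), gamma_grid = 2^(-10:3),
                    epsilon_grid = c(0.01, 0.1, 0.5, 1),
                    k_folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (stats::sd(y) == 0) stop("fit_svr: response has zero variance", call. = FALSE)
  levels <- if (!is.null(shade)) sort(unique(shade))
  D <- if (is.null(shade)) X else cbind(X, shade_dummies(shade, levels))
  n <- nrow(D)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      epsilon = epsilon_grid, KEEP.OUT.ATTRS = FALSE)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  cv_mse <- vapply(seq_len(nrow(grid)), function(gi) {
    se <- numeric(n)
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      m <- e1071::svm(D[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "radial", cost = grid$cost[gi],
                      gamma = grid$gamma[gi], epsilon = grid$epsilon[gi])
      se[!tr] <- (y[!tr] - stats::predict(m, D[!tr, , drop = FALSE]))^2
    }
    mean(se)
  }, 0)
  best <- which.min(cv_mse)
  svm_fit <- e1071::svm(D, y, type = "eps-regression", kernel = "radial",
                        cost = grid$cost[best], gamma = grid$gamma[best],
                        epsilon = grid$epsilon[best])
  structure(list(svm = svm_fit, features = colnames(X), shade_levels = levels,
                 tuning = as.list(grid[best, ]), cv_mse = cv_mse[best],
                 fitted = as.numeric(stats::predict(svm_fit, D))),
            class = "spad_svr")
}

#' @export
predict.spad_svr <- function(object, X, shade = NULL, ...) {
  X <- as.matrix(X)[, object$features, drop = FALSE]
  D <- if (is.null(object$shade_levels)) X
       else cbind(X, shade_dummies(shade, object$shade_levels))
  as.numeric(stats::predict(object$svm, D))
}

#' Build a model fit report with per-split metrics
#'
#' @param fit a fitted `spad_*` model.
#' @param train,test lists with elements `X`, `y` and optionally `shade`.
#' @return an object of class `model_fit_report`: model family, feature set,
#'   hyperparameters and R2/RMSE/MAPE on each supplied split.
#' @export
model_report <- function(fit, train, test = NULL) {
  family <- sub("^spad_", "", class(fit)[1])
  eval_split <- function(s) {
    pred <- stats::predict(fit, s$X, shade = s$shade)
    regression_metrics(s$y, pred)
  }
  rep <- list(family = family, features = fit$features,
              shade_aware = !is.null(train$shade) ||
                inherits(fit, "spad_lmm"),
              hyperparameters = fit$tuning %||% NULL,
              train = eval_split(train))
  if (!is.null(test)) rep$test <- eval_split(test)
  structure(rep, class = "model_fit_report")
}

#' @export
print.model_fit_report <- function(x, ...) {
  cat(sprintf("%s model (%s shade) on %d feature(s)\n", toupper(x$family),
              if (x$shade_aware) "with" else "without", length(x$features)))
  fmt <- function(m) sprintf("R2 %.4f, RMSE %.4f, MAPE %.2f%%",
                             m["r2"], m["rmse"], m["mape"])
  cat("  modeling: ", fmt(x$train), "\n")
  if (!is.null(x$test)) cat("  test:     ", fmt(x$test), "\n")
  invisible(x)
}
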