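#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t test,
#' `t = r * sqrt((n-2)/(1-r^2))` against Student-t with `n-2` degrees of
#' freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L) stop("pearson_with_p: need equal lengths >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_with_p: zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Variance inflation factors
#'
#' For each column j, regresses it (with intercept) on all other columns
#' and returns `VIF_j = 1 / (1 - R2_j)`. Near-singular auxiliary fits
#' (`R2 >= 1 - 1e-6`) are reported as the cap `1e6`. Interpretation bands:
#' VIF < 10 no multicollinearity, 10–20 some autocorrelation, > 20 serious
#' multicollinearity.
#'
#' @param X numeric matrix or data frame, `n > p`, no constant column.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("vif: need more rows than columns", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("vif: constant column(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  if (p == 1L) return(stats::setNames(1, colnames(X)))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-6) 1e6 else 1 / (1 - r2)
  }, 0)
  stats::setNames(out, colnames(X))
}

#' Classify VIF values into multicollinearity bands
#'
#' @param v numeric VIF values.
#' @return character vector: `"none"` (< 10), `"some"` (10–20),
#'   `"serious"` (> 20).
#' @export
vif_class <- function(v) {
  ifelse(v < 10, "none", ifelse(v <= 20, "some", "serious"))
}

#' Significance pre-filter
#'
#' Drops features whose correlation with the response is not significant
#' (`p >= alpha`) before penalized selection. Optionally applies Holm
#' multiplicity correction first (off by default).
#'
#' @param p_values named vector of per-feature p-values.
#' @param alpha significance level (default 0.05).
#' @param holm apply Holm correction before filtering.
#' @return names of surviving features; dropped names are reported via
#'   `message()`.
#' @export
prefilter <- function(p_values, alpha = 0.05, holm = FALSE) {
  p <- if (holm) stats::p.adjust(p_values, method = "holm") else p_values
  keep <- names(p)[p < alpha]
  dropped <- setdiff(names(p), keep)
  if (length(dropped)) {
    message("prefilter: dropped ", paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("prefilter: all features dropped", call. = FALSE)
  keep
}

# Soft-thresholding operator.
soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Lasso solution by cyclic coordinate descent
#'
#' Minimizes `||y - X beta||^2 + lambda * sum(|beta_j|)` (the penalty enters
#' once, not scaled by n) by cyclic coordinate descent with soft
#' thresholding. `X` is assumed already standardized and `y` centered; no
#' intercept is fitted.
#'
#' @param X standardized design matrix.
#' @param y centered response.
#' @param lambda non-negative penalty.
#' @param beta0 optional warm start.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_sweeps maximum number of full coordinate sweeps.
#' @return list with `beta` (named), `iterations`, `converged`.
#' @export
lasso_cd <- function(X, y, lambda, beta0 = NULL, tol = 1e-8, max_sweeps = 1e5,
                     XtX = NULL, Xty = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (lambda < 0) stop("lasso_cd: lambda must be >= 0", call. = FALSE)
  # covariance-form updates: each sweep costs O(p^2) after the one-off
  # O(n p^2) cross-product, which keeps path + CV fits cheap
  if (is.null(XtX)) XtX <- crossprod(X)
  if (is.null(Xty)) Xty <- as.numeric(crossprod(X, y))
  if (any(diag(XtX) == 0)) stop("lasso_cd: zero-norm column", call. = FALSE)
  beta <- if (is.null(beta0)) numeric(p) else as.numeric(beta0)
  fit <- .cd_sweeps(XtX, Xty, beta, lambda, tol, as.integer(max_sweeps))
  list(beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
       iterations = fit$iterations, converged = fit$converged)
}

# Check the Karush-Kuhn-Tucker conditions of a lasso solution; returns the
# worst violation (0 is perfect).
lasso_kkt_violation <- function(X, y, beta, lambda) {
  g <- 2 * crossprod(X, y - X %*% beta)  # -gradient of ||y - Xb||^2
  active <- beta != 0
  viol <- 0
  if (any(active)) {
    viol <- max(viol, max(abs(g[active] - lambda * sign(beta[active]))))
  }
  if (any(!active)) viol <- max(viol, max(pmax(abs(g[!active]) - lambda, 0)))
  viol
}

#' Lasso feature selection with cross-validated penalty
#'
#' Standardizes the feature columns to mean 0 and variance 1 and centers the
#' response, fits the Lasso path over a log-spaced grid of 100 penalties
#' from `lambda_max` (the smallest penalty that zeroes every coefficient,
#' `max_j |2 x_j' y|`) down to `1e-4 * lambda_max`, chooses the penalty
#' minimizing k-fold cross-validated MSE, and refits OLS on the retained
#' (nonzero) columns to report the model's multiple correlation
#' `R = sqrt(R2)`.
#'
#' Exactly collinear (aliased) columns — pairs whose standardized versions
#' are identical up to sign, such as two indices related by an affine map —
#' make the penalized optimum non-unique (any split of the shared weight is
#' a minimizer). As in ordinary linear modeling, later aliases are dropped
#' before the fit and reported in `$aliased`.
#'
#' @param X feature matrix or data frame (raw scale).
#' @param y response (SPAD).
#' @param lambda_grid optional penalty grid; built automatically if `NULL`.
#' @param k_folds folds for cross-validation (default 10).
#' @param seed seed for the fold assignment.
#' @param n_lambda grid size when building the grid.
#' @param coef_tol coefficients below this absolute value (standardized
#'   scale) are treated as numerically zero when forming the retained set;
#'   exactly collinear column pairs otherwise leave rounding-level residue
#'   on the dropped member.
#' @return an object of class `screen_report`: list with `lambda_grid`,
#'   `beta_path` (p x n_lambda), `cv_mse`, `lambda_star`, `beta`
#'   (standardized scale, at `lambda_star`), `retained`, `multiple_r`,
#'   `kkt_violation`, and the standardization constants.
#' @export
lasso_select <- function(X, y, lambda_grid = NULL, k_folds = 10L, seed = 1L,
                         n_lambda = 100L, coef_tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("lasso_select: constant feature column", call. = FALSE)
  Xs <- scale(X, center = ctr, scale = scl)
  aliased <- character(0)
  if (ncol(Xs) > 1L) {
    cc <- abs(stats::cor(Xs))
    drop <- rep(FALSE, ncol(Xs))
    for (j in 2:ncol(Xs)) {
      if (any(cc[j, 1:(j - 1)][!drop[1:(j - 1)]] > 1 - 1e-8)) drop[j] <- TRUE
    }
    aliased <- colnames(X)[drop]
    if (length(aliased)) {
      message("lasso_select: dropping aliased column(s): ",
              paste(aliased, collapse = ", "))
      X <- X[, !drop, drop = FALSE]
      Xs <- Xs[, !drop, drop = FALSE]
      ctr <- ctr[!drop]; scl <- scl[!drop]
    }
  }
  ybar <- mean(y)
  yc <- y - ybar
  lambda_max <- max(abs(2 * crossprod(Xs, yc)))
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(lambda_max), log(1e-4 * lambda_max),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  cv_se <- matrix(0, n, length(lambda_grid))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    Xtr <- Xs[tr, , drop = FALSE]; ytr <- yc[tr]
    Xte <- Xs[!tr, , drop = FALSE]; yte <- yc[!tr]
    XtX <- crossprod(Xtr); Xty <- as.numeric(crossprod(Xtr, ytr))
    b <- NULL
    for (li in seq_along(lambda_grid)) {
      fit <- lasso_cd(Xtr, ytr, lambda_grid[li], beta0 = b, XtX = XtX, Xty = Xty)
      b <- fit$beta
      cv_se[!tr, li] <- as.numeric(yte - Xte %*% b)^2
    }
  }
  cv_mse <- colMeans(cv_se)
  li_star <- which.min(cv_mse)
  lambda_star <- lambda_grid[li_star]

  beta_path <- matrix(0, ncol(Xs), length(lambda_grid),
                      dimnames = list(colnames(X), NULL))
  XtX <- crossprod(Xs); Xty <- as.numeric(crossprod(Xs, yc))
  b <- NULL
  for (li in seq_along(lambda_grid)) {
    fit <- lasso_cd(Xs, yc, lambda_grid[li], beta0 = b, XtX = XtX, Xty = Xty)
    b <- fit$beta
    beta_path[, li] <- b
  }
  beta_star <- beta_path[, li_star]
  retained <- names(beta_star)[abs(beta_star) > coef_tol]
  if (!length(retained)) {
    warning("lasso_select: empty model at lambda*; falling back to smallest grid lambda")
    li_star <- length(lambda_grid)
    lambda_star <- lambda_grid[li_star]
    beta_star <- beta_path[, li_star]
    retained <- names(beta_star)[abs(beta_star) > coef_tol]
  }
  refit <- stats::lm.fit(cbind(1, X[, retained, drop = FALSE]), y)
  r2 <- 1 - sum(refit$residuals^2) / sum((y - ybar)^2)
  structure(list(
    lambda_grid = lambda_grid, beta_path = beta_path, cv_mse = cv_mse,
    lambda_star = lambda_star, beta = beta_star, retained = retained,
    aliased = aliased, multiple_r = sqrt(max(r2, 0)),
    kkt_violation = lasso_kkt_violation(Xs, yc, beta_star, lambda_star),
    center = ctr, scale = scl
  ), class = "screen_report")
}

#' Full screening stage for one index set
#'
#' Per-feature Pearson correlation and significance against SPAD, VIF
#' diagnosis of the full set, significance pre-filter, and Lasso selection
#' with cross-validated penalty on the survivors, plus VIFs of the retained
#' set.
#'
#' @param features feature data frame (columns = indices).
#' @param y SPAD response.
#' @param alpha pre-filter significance level.
#' @param holm apply Holm correction in the pre-filter.
#' @param ... passed to [lasso_select()].
#' @return a `screen_report` augmented with `stats` (per-feature r, p, VIF),
#'   `prefiltered` (survivor names) and `retained_vif`.
#' @export
screen_features <- function(features, y, alpha = 0.05, holm = FALSE, ...) {
  X <- as.matrix(features)
  keep_rows <- stats::complete.cases(X) & is.finite(y)
  n_dropped <- sum(!keep_rows)
  if (n_dropped > 0) {
    message("screen_features: dropped ", n_dropped, " record(s) with invalid indices")
  }
  X <- X[keep_rows, , drop = FALSE]
  yk <- y[keep_rows]
  rp <- lapply(seq_len(ncol(X)), function(j) pearson_with_p(X[, j], yk))
  st <- data.frame(
    feature = colnames(X),
    r = vapply(rp, `[[`, 0, "r"),
    p = vapply(rp, `[[`, 0, "p"),
    vif = vif(X),
    row.names = NULL
  )
  surv <- prefilter(stats::setNames(st$p, st$feature), alpha = alpha, holm = holm)
  rep <- lasso_select(X[, surv, drop = FALSE], yk, ...)
  rep$stats <- st
  rep$prefiltered <- surv
  rep$retained_vif <- if (length(rep$retained) > 1L) vif(X[, rep$retained, drop = FALSE])
                      else stats::setNames(rep(1, length(rep$retained)), rep$retained)
  rep$n_dropped_records <- n_dropped
  rep
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screening report\n")
  if (!is.null(x$stats)) {
    cat(sprintf("  features: %d, pre-filter survivors: %d\n",
                nrow(x$stats), length(x$prefiltered)))
  }
  cat(sprintf("  lambda*: %.4g, retained: %s\n", x$lambda_star,
              paste(x$retained, collapse = ", ")))
  cat(sprintf("  multiple R: %.4f\n", x$multiple_r))
  invisible(x)
}

#' Serialize a screening report
#'
#' Writes the per-feature statistics and the coefficient path as CSV and the
#' scalar summary as JSON.
#'
#' @param report a `screen_report`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_screen_report <- function(report, dir, prefix = "screen") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    stats = file.path(dir, paste0(prefix, "_stats.csv")),
    path = file.path(dir, paste0(prefix, "_path.csv")),
    summary = file.path(dir, paste0(prefix, "_summary.json"))
  )
  if (!is.null(report$stats)) utils::write.csv(report$stats, paths["stats"], row.names = FALSE)
  path_df <- data.frame(lambda = report$lambda_grid, t(report$beta_path))
  utils::write.csv(path_df, paths["path"], row.names = FALSE)
  jsonlite::write_json(
    list(lambda_star = report$lambda_star, retained = report$retained,
         multiple_r = report$multiple_r, kkt_violation = report$kkt_violation,
         retained_vif = as.list(report$retained_vif)),
    paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
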