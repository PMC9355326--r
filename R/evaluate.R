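#' Regression evaluation metrics
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` (computed against the
#' mean of the evaluated split, so test-set R2 may be negative),
#' `RMSE = sqrt(mean((y - yhat)^2))` in SPAD units, and
#' `MAPE = 100 * mean(|y - yhat| / |y|)` in percent.
#'
#' @param y_true observed values (all nonzero, or MAPE is undefined).
#' @param y_pred predicted values, same length >= 2.
#' @return named vector `c(r2, rmse, mape)`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n != length(y_pred) || n < 2L) {
    stop("regression_metrics: need equal lengths >= 2", call. = FALSE)
  }
  if (any(y_true == 0)) {
    stop("regression_metrics: zero observed value makes MAPE undefined", call. = FALSE)
  }
  err <- y_true - y_pred
  c(r2 = 1 - sum(err^2) / sum((y_true - mean(y_true))^2),
    rmse = sqrt(mean(err^2)),
    mape = 100 * mean(abs(err) / abs(y_true)))
}

#' Random modeling/test split
#'
#' Partitions ids at a `ratio : 1` rate (default 3:1, e.g. 150/50 out of
#' 200) by uniform random sampling. The stratified variant balances shade
#' levels: each stratum contributes its proportional share, with the
#' rounding remainder assigned in seeded random stratum order.
#'
#' @param ids vector of record ids (>= 4).
#' @param ratio modeling:test ratio (modeling fraction is
#'   `ratio / (ratio + 1)`).
#' @param seed RNG seed.
#' @param stratify_by optional grouping vector (same length as `ids`), e.g.
#'   shade levels.
#' @return an object of class `split_plan`: list with `modeling`, `test`,
#'   `seed`, `stratified`.
#' @export
split_plan <- function(ids, ratio = 3, seed = 1L, stratify_by = NULL) {
  n <- length(ids)
  if (n < 4L) stop("split_plan: need at least 4 ids", call. = FALSE)
  if (!is.numeric(ratio) || ratio <= 0) stop("split_plan: infeasible ratio", call. = FALSE)
  n_model <- round(n * ratio / (ratio + 1))
  if (n_model < 1L || n_model >= n) stop("split_plan: infeasible ratio", call. = FALSE)
  modeling <- with_seed(seed, {
    if (is.null(stratify_by)) {
      sample(ids, n_model)
    } else {
      strata <- split(ids, stratify_by)
      base <- vapply(strata, function(s) floor(length(s) * ratio / (ratio + 1)), 0)
      rem <- n_model - sum(base)
      extra <- rep(0L, length(strata))
      if (rem > 0) {
        extra[sample(seq_along(strata), rem)] <- 1L
      }
      unlist(lapply(seq_along(strata), function(i) {
        sample(strata[[i]], base[i] + extra[i])
      }), use.names = FALSE)
    }
  })
  structure(list(modeling = modeling, test = setdiff(ids, modeling),
                 seed = as.integer(seed), stratified = !is.null(stratify_by)),
            class = "split_plan")
}

#' One-way ANOVA across shade levels
#'
#' Classic one-way F test, `F = MS_between / MS_within` with `(k-1, N-k)`
#' degrees of freedom, assuming equal variances.
#'
#' @param values numeric vector (e.g. measured SPAD).
#' @param groups grouping vector (e.g. shade level), >= 2 groups with >= 2
#'   values each.
#' @return list with `F`, `p`, `df` (numerator, denominator).
#' @export
anova_oneway <- function(values, groups) {
  f <- factor(groups)
  if (nlevels(f) < 2L || any(table(f) < 2L)) {
    stop("anova_oneway: need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  if (all(tapply(values, f, stats::var) == 0)) {
    stop("anova_oneway: zero within-group variance in every group", call. = FALSE)
  }
  ht <- stats::oneway.test(values ~ f, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Relative change in percent
#'
#' `100 * (value - reference) / reference`, reported with half-up rounding
#' to 2 decimals (the convention of printed comparison tables). A positive
#' result reads "value is X% higher than reference"; for "X% lower", pass
#' `direction = "lower"`, which returns
#' `100 * (reference - value) / reference`.
#'
#' @param reference baseline value (nonzero).
#' @param value compared value.
#' @param direction `"higher"` (default) or `"lower"`.
#' @param digits decimals for half-up rounding (`NULL` to skip rounding).
#' @return percent change.
#' @export
relative_change <- function(reference, value, direction = c("higher", "lower"),
                            digits = 2) {
  direction <- match.arg(direction)
  stopifnot_scalar(reference, "reference")
  stopifnot_scalar(value, "value")
  if (reference == 0) stop("relative_change: zero reference", call. = FALSE)
  pct <- if (direction == "higher") 100 * (value - reference) / reference
         else 100 * (reference - value) / reference
  if (is.null(digits)) pct else round_half_up(pct, digits)
}
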