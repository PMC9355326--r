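#' Default end-to-end run configuration
#'
#' A single nested list drives the whole pipeline; every stochastic stage
#' draws its own sub-seed from the master `seed`. Override any entry by
#' passing replacements, e.g. `default_config(seed = 7)` or a reduced SVR
#' grid for quick runs.
#'
#' @param ... named entries replacing defaults (top-level only, merged
#'   shallowly per section).
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    synthetic = list(
      render = TRUE,            # render scenes vs analytic band means
      noise_sd = 1.0,           # per-leaf SPAD meter noise
      seedling_sd = 0.10,       # per-seedling band factor (lognormal sd)
      width = 96L, height = 96L
    ),
    shade = list(
      levels = c(0, 0.25, 0.50, 0.75),
      mean_spad = c(18.39, 25.76, 31.81, 29.26),
      sd_spad = 3.6,
      n_per_level = 50L,
      illumination = c(1.0, 0.75, 0.5, 0.25)
    ),
    segmentation = list(n_bins = 256L),
    indices = list(literature_formulas = FALSE),
    screening = list(alpha = 0.05, holm = FALSE, k_folds = 10L),
    models = list(
      roster = c("olr", "lmm", "rf", "svr"),
      rf_trees = 500L,
      svr_cost = 2^(-3:10), svr_gamma = 2^(-10:3),
      svr_epsilon = c(0.01, 0.1, 0.5, 1), svr_folds = 10L
    ),
    split = list(ratio = 3, stratify = FALSE),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg$synthetic), is.list(cfg$shade), is.list(cfg$models))
  stopifnot_scalar(cfg$seed, "seed")
  bad <- setdiff(cfg$models$roster, c("olr", "lmm", "rf", "svr"))
  if (length(bad)) stop("unknown model family: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  shade_config(cfg$shade$levels, cfg$shade$mean_spad, cfg$shade$sd_spad,
               cfg$shade$n_per_level, cfg$shade$illumination)  # validates
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Entries present in the file override the defaults of [default_config()].
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_config, raw)
}

config_shade <- function(cfg) {
  shade_config(cfg$shade$levels, cfg$shade$mean_spad, cfg$shade$sd_spad,
               cfg$shade$n_per_level, cfg$shade$illumination)
}

#' Generate the synthetic dataset a configuration describes
#'
#' @param cfg a `run_config`.
#' @param out optional directory; when given, scenes and manifest are
#'   written there via [write_dataset()].
#' @param force overwrite a non-empty output directory.
#' @return a `canopy_dataset` (invisibly when `out` is given).
#' @export
cmd_generate <- function(cfg = default_config(), out = NULL, force = FALSE) {
  sc <- config_shade(cfg)
  seeds <- derive_seeds(cfg$seed, 6)
  ds <- synth_dataset(sc, spectral_model(), noise_sd = cfg$synthetic$noise_sd,
                      seed = seeds[1],
                      width = cfg$synthetic$width, height = cfg$synthetic$height,
                      seedling_sd = cfg$synthetic$seedling_sd)
  message(sprintf("generated %d scenes over %d shade levels; per-level mean SPAD: %s",
                  nrow(ds$records), length(sc$levels),
                  paste(sprintf("%.2f", tapply(ds$records$spad_measured,
                                               ds$records$shade, mean)),
                        collapse = ", ")))
  if (!is.null(out)) {
    write_dataset(ds, out, force = force)
    return(invisible(ds))
  }
  ds
}

# Fit one family on one source/mode and report both splits.
fit_family <- function(family, Xtr, ytr, shade_tr, Xte, yte, shade_te,
                       cfg, seeds, shade_aware) {
  m <- cfg$models
  fit <- switch(family,
    olr = fit_olr(Xtr, ytr, shade = if (shade_aware) shade_tr),
    # without grouping the mixed model has no random term; its shade-blind
    # counterpart is plain OLR
    lmm = if (shade_aware) fit_lmm(Xtr, shade_tr, ytr) else fit_olr(Xtr, ytr),
    rf = fit_rf(Xtr, ytr, shade = if (shade_aware) shade_tr,
                n_trees = m$rf_trees, seed = seeds[1]),
    svr = fit_svr(Xtr, ytr, shade = if (shade_aware) shade_tr,
                  cost_grid = m$svr_cost, gamma_grid = m$svr_gamma,
                  epsilon_grid = m$svr_epsilon, k_folds = m$svr_folds,
                  seed = seeds[2])
  )
  model_report(fit,
               train = list(X = Xtr, y = ytr,
                            shade = if (shade_aware) shade_tr),
               test = list(X = Xte, y = yte,
                           shade = if (shade_aware) shade_te))
}

#' Run the full experiment described by a configuration
#'
#' Executes generate -> segment -> extract indices -> screen -> fit the
#' model roster (per image source, with and without shade) -> evaluate on a
#' 3:1 modeling/test split. Screening (correlations, VIF, pre-filter,
#' Lasso) uses the modeling samples only.
#'
#' @param cfg a `run_config`.
#' @param dataset optional pre-built `canopy_dataset` (skips generation).
#' @return list with `features` (per-seedling index table), `split`,
#'   `screens` (per-source `screen_report`), `reports` (per-combination
#'   `model_fit_report`), `summary` (one row per family x source x shade
#'   mode), and `anova` on measured SPAD across shade levels.
#' @export
run_experiment <- function(cfg = default_config(), dataset = NULL) {
  cfg <- validate_config(cfg)
  seeds <- derive_seeds(cfg$seed + 1L, 8)
  if (is.null(dataset)) dataset <- cmd_generate(cfg)

  features <- if (isTRUE(cfg$synthetic$render) || !is.null(dataset$scenes)) {
    extract_features(dataset, n_bins = cfg$segmentation$n_bins,
                     literature_formulas = cfg$indices$literature_formulas)
  } else {
    features_from_band_means(dataset, cfg$indices$literature_formulas)
  }

  an <- anova_oneway(features$spad_measured, features$shade)
  plan <- split_plan(features$id, ratio = cfg$split$ratio, seed = seeds[1],
                     stratify_by = if (isTRUE(cfg$split$stratify)) features$shade)
  tr <- features$id %in% plan$modeling
  nm <- index_names()
  screens <- list()
  reports <- list()
  rows <- list()
  for (source in c("rgb", "ms")) {
    cols <- nm[[source]]
    scr <- screen_features(features[tr, cols], features$spad_measured[tr],
                           alpha = cfg$screening$alpha, holm = cfg$screening$holm,
                           k_folds = cfg$screening$k_folds, seed = seeds[2])
    screens[[source]] <- scr
    sel <- scr$retained
    ok <- stats::complete.cases(features[, sel, drop = FALSE])
    dat <- features[ok, ]
    tr_ok <- dat$id %in% plan$modeling
    Xtr <- dat[tr_ok, sel, drop = FALSE]; ytr <- dat$spad_measured[tr_ok]
    Xte <- dat[!tr_ok, sel, drop = FALSE]; yte <- dat$spad_measured[!tr_ok]
    shade_tr <- dat$shade[tr_ok]; shade_te <- dat$shade[!tr_ok]
    for (mode in c("without_shade", "with_shade")) {
      for (family in cfg$models$roster) {
        rep <- fit_family(family, Xtr, ytr, shade_tr, Xte, yte, shade_te,
                          cfg, seeds[3:4], shade_aware = mode == "with_shade")
        key <- paste(family, source, mode, sep = ".")
        reports[[key]] <- rep
        rows[[key]] <- data.frame(
          family = family, source = source, shade_mode = mode,
          r2_model = rep$train["r2"], rmse_model = rep$train["rmse"],
          mape_model = rep$train["mape"],
          r2_test = rep$test["r2"], rmse_test = rep$test["rmse"],
          mape_test = rep$test["mape"], row.names = NULL)
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(features = features, split = plan, screens = screens,
       reports = reports, summary = summary, anova = an, config = cfg)
}

#' Run an experiment and write its artifacts to disk
#'
#' Writes the feature table, per-source screening reports, per-model
#' reports (JSON), predictions (CSV) and the summary table.
#'
#' @param cfg a `run_config`.
#' @param out output directory.
#' @param force overwrite a non-empty directory.
#' @return the [run_experiment()] result, invisibly.
#' @export
cmd_run <- function(cfg = default_config(), out, force = FALSE) {
  if (dir.exists(out) && length(dir(out)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)", call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- run_experiment(cfg)
  utils::write.csv(res$features, file.path(out, "features.csv"), row.names = FALSE)
  for (source in names(res$screens)) {
    write_screen_report(res$screens[[source]], out, prefix = paste0("screen_", source))
  }
  reports_json <- lapply(res$reports, function(r) {
    list(family = r$family, features = r$features, shade_aware = r$shade_aware,
         hyperparameters = r$hyperparameters,
         train = as.list(r$train), test = as.list(r$test))
  })
  jsonlite::write_json(reports_json, file.path(out, "model_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(res$summary, file.path(out, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(res$anova, file.path(out, "anova.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
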