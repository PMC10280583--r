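#' Configuration of the full benchmark experiment
#'
#' Describes one end-to-end run: split the dataset, fit every preprocessing
#' x {PLSR, PCR} baseline with cross-validated component selection, train
#' the convolutional autoencoder once (unsupervised) on raw calibration
#' spectra, fit one MLR per target on its latent variables, and score
#' everything on the calibration and prediction sets.
#'
#' @param input path to a wide-CSV spectral dataset (see [read_spectra()]);
#'   may be `NULL` when a `spectra_set` is passed to [run_experiment()]
#'   directly.
#' @param n_calibration calibration-set size.
#' @param preprocessing preprocessing variants for the baselines.
#' @param baselines regression families fitted on preprocessed spectra.
#' @param k_max,cv_folds component-selection grid and fold count.
#' @param cae a [cae_config()] for the proposed method.
#' @param targets target names; default uses every target column.
#' @param seeds named integer seeds: `split`, `cae` (training), `cv` (fold
#'   shuffle).
#' @param out_dir optional output directory for persisted artifacts.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(input = NULL, n_calibration = 60L,
                              preprocessing = c("none", "msc", "snv",
                                                "savgol", "mean_center"),
                              baselines = c("plsr", "pcr"), k_max = 10L,
                              cv_folds = 5L, cae = cae_config(),
                              targets = NULL,
                              seeds = c(split = 11L, cae = 21L, cv = 31L),
                              out_dir = NULL) {
  stopifnot(length(preprocessing) + length(baselines) >= 1,
            all(c("split", "cae", "cv") %in% names(seeds)))
  structure(list(input = input, n_calibration = as.integer(n_calibration),
                 preprocessing = preprocessing, baselines = baselines,
                 k_max = as.integer(k_max), cv_folds = as.integer(cv_folds),
                 cae = cae, targets = targets,
                 seeds = vapply(seeds, as.integer, integer(1)),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the `cae`
#' block holds [cae_config()] fields.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cae)) y$cae <- do.call(cae_config, y$cae)
  if (!is.null(y$seeds)) y$seeds <- unlist(y$seeds)
  do.call(experiment_config, y)
}

#' Run the full benchmark experiment
#'
#' For each target the report holds one row per preprocessing x baseline
#' combination (with the CV-selected component count) plus one row for the
#' proposed autoencoder + MLR method. The autoencoder is trained once per
#' dataset on raw calibration spectra — reference values are never seen by
#' it — and its latent variables are reused across all targets. All fitted
#' state (preprocessing, centering, scaling) is learned from the calibration
#' set only. When `config$out_dir` is set, the split, latents, training log,
#' report and RMSPE summary are written there.
#'
#' @param config an [experiment_config()].
#' @param data optional [spectra_set]; read from `config$input` when absent.
#' @return list of class `experiment_result` with `report` (data.frame),
#'   `rmspe` (reconstruction summary), `cae_model`, `split`, `latents`,
#'   `log` (per-stage messages).
#' @export
run_experiment <- function(config, data = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  log <- character()
  note <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    log <<- c(log, line)
    message(line)
  }
  if (is.null(data)) {
    if (is.null(config$input)) stop("no input path and no data supplied")
    data <- suppressMessages(read_spectra(config$input))
  }
  if (is.null(data$targets)) stop("dataset has no targets")
  targets <- config$targets %||% names(data$targets)
  note("input", n_samples(data), " samples x ", n_channels(data),
       " channels, targets: ", paste(targets, collapse = ", "))

  split <- random_split(data, config$n_calibration, config$seeds[["split"]])
  cal <- subset_samples(data, split$calibration_ids)
  pred <- subset_samples(data, split$prediction_ids)
  note("split", length(split$calibration_ids), "/",
       length(split$prediction_ids), " (seed ", split$seed, ")")

  # proposed method: unsupervised CAE on raw calibration spectra
  cae_cfg <- config$cae
  if (cae_cfg$input_length != n_channels(data))
    stop("cae input_length (", cae_cfg$input_length,
         ") does not match channel count (", n_channels(data), ")")
  model <- train_cae(build_cae(cae_cfg), cal, seed = config$seeds[["cae"]])
  note("cae", "trained ", nrow(model$training_log), " epochs, final val loss ",
       format(model$training_log$val_loss[nrow(model$training_log)],
              digits = 4))
  lat_cal <- encode(model, cal)
  lat_pred <- encode(model, pred)
  rmspe_tab <- rbind(
    rmspe_summary(rmspe_by_sample(cal$absorbance, reconstruct(model, cal)),
                  "calibration"),
    rmspe_summary(rmspe_by_sample(pred$absorbance, reconstruct(model, pred)),
                  "prediction"))
  note("cae", "reconstruction mean RMSPE cal ",
       sprintf("%.2f%%", rmspe_tab$mean[1]), ", pred ",
       sprintf("%.2f%%", rmspe_tab$mean[2]))

  rows <- list()
  for (tg in targets) {
    y_cal <- cal$targets[[tg]]
    y_pred <- pred$targets[[tg]]
    for (pp in config$preprocessing) {
      spec <- preprocess_fit(pp, cal$absorbance)
      Xc <- preprocess_apply(spec, cal$absorbance)
      Xp <- preprocess_apply(spec, pred$absorbance)
      for (fam in config$baselines) {
        cv <- select_components_cv(Xc, y_cal, fam, k_max = config$k_max,
                                   folds = config$cv_folds,
                                   seed = config$seeds[["cv"]])
        fitter <- if (fam == "plsr") fit_plsr else fit_pcr
        m <- fitter(Xc, y_cal, cv$selected_count, preprocessing = spec)
        ev <- evaluate_predictions(y_cal, as.numeric(Xc %*% m$coefficients +
                                                       m$intercept),
                                   y_pred, as.numeric(Xp %*% m$coefficients +
                                                        m$intercept))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(target = tg, preprocessing = pp, regressor = fam,
                     n_components = cv$selected_count), ev)
      }
    }
    mlr <- fit_mlr(lat_cal, y_cal)
    ev <- evaluate_predictions(y_cal, predict(mlr, lat_cal),
                               y_pred, predict(mlr, lat_pred))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(target = tg, preprocessing = "raw", regressor = "cae_mlr",
                 n_components = cae_cfg$latent_dim), ev)
    note("target", tg, ": best pred R2 ",
         format(max(vapply(rows[vapply(rows, function(r)
           r$target == tg, logical(1))], function(r) r$r2_pred, numeric(1))),
           digits = 4))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  note("done", "elapsed ",
       format(round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)),
       "s")
  result <- structure(list(report = report, rmspe = rmspe_tab,
                           cae_model = model, split = split,
                           latents = rbind(lat_cal, lat_pred), log = log),
                      class = "experiment_result")
  if (!is.null(config$out_dir)) write_experiment(result, config$out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_report <- function(report) {
  out <- report
  for (cc in c("r2_cal", "r2_pred")) out[[cc]] <- sprintf("%.4f", out[[cc]])
  for (cc in c("rmse_cal", "rmse_pred"))
    out[[cc]] <- sprintf("%.4f", out[[cc]])
  out
}

write_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_report(result$report),
                   file.path(dir, "report.csv"), row.names = FALSE,
                   quote = FALSE)
  rs <- result$rmspe
  for (cc in c("min", "max", "mean", "std")) rs[[cc]] <- sprintf("%.2f", rs[[cc]])
  utils::write.csv(rs, file.path(dir, "rmspe_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  write_split(result$split, file.path(dir, "split.json"))
  lat <- data.frame(sample_id = rownames(result$latents), result$latents)
  utils::write.csv(lat, file.path(dir, "latents.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(result$log, file.path(dir, "log.txt"))
  writeLines(render_tables(result$report), file.path(dir, "tables.md"))
  save_cae(result$cae_model, file.path(dir, "cae_model"))
  invisible(dir)
}

#' Render the benchmark report as per-target markdown tables
#'
#' One block per target; within each block the best (highest) R-squared and
#' best (lowest) RMSE per column are flagged with `*`, ties all flagged. An
#' improvement summary is appended comparing the proposed method's mean
#' R-squared against the mean over PLSR rows and over PCR rows, as
#' `(proposed - reference) / reference * 100`.
#'
#' @param report the `report` data.frame of an [run_experiment()] result.
#' @return character vector of markdown lines.
#' @export
render_tables <- function(report) {
  stopifnot(nrow(report) > 0)
  lines <- character()
  flag <- function(v, best) ifelse(v == best, paste0("**", sprintf("%.4f", v),
                                                     "**"),
                                   sprintf("%.4f", v))
  for (tg in unique(report$target)) {
    blk <- report[report$target == tg, ]
    lines <- c(lines, paste0("## ", tg), "",
               "| Preprocessing | Regressor | LV/PC | R2 cal | R2 pred | RMSE cal | RMSE pred |",
               "|---|---|---|---|---|---|---|")
    cells <- data.frame(
      r2c = flag(blk$r2_cal, max(blk$r2_cal)),
      r2p = flag(blk$r2_pred, max(blk$r2_pred)),
      rc = flag(blk$rmse_cal, min(blk$rmse_cal)),
      rp = flag(blk$rmse_pred, min(blk$rmse_pred)))
    for (i in seq_len(nrow(blk)))
      lines <- c(lines, sprintf("| %s | %s | %d | %s | %s | %s | %s |",
                                blk$preprocessing[i], blk$regressor[i],
                                blk$n_components[i], cells$r2c[i],
                                cells$r2p[i], cells$rc[i], cells$rp[i]))
    lines <- c(lines, "")
  }
  prop <- report[report$regressor == "cae_mlr", ]
  if (nrow(prop) > 0) {
    lines <- c(lines, "## Improvement of the proposed method (mean R2, %)", "",
               "| Reference | Calibration | Prediction |", "|---|---|---|")
    for (fam in intersect(c("plsr", "pcr"), report$regressor)) {
      ref <- report[report$regressor == fam, ]
      imp <- function(col) (mean(prop[[col]]) - mean(ref[[col]])) /
        mean(ref[[col]]) * 100
      lines <- c(lines, sprintf("| vs %s | %.2f | %.2f |", toupper(fam),
                                imp("r2_cal"), imp("r2_pred")))
    }
    lines <- c(lines, "")
  }
  lines
}
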