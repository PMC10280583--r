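#' Read a spectral dataset from a wide CSV file
#'
#' The wide dialect stores one sample per row. Columns are, in order: an
#' optional `sample_id` column, one numeric-named column per wavelength (nm),
#' and optional trailing reference-value columns whose header carries the
#' prefix `target:` (e.g. `target:moisture`).
#'
#' @param path path to an existing CSV file.
#' @param dialect file layout; only `"wide_csv"` is supported.
#' @return a validated [spectra_set].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, dialect = "wide_csv") {
  dialect <- match.arg(dialect, "wide_csv")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  id_col <- which(nm == "sample_id")
  target_cols <- grep("^target:", nm)
  wl_cols <- setdiff(seq_along(nm), c(id_col, target_cols))
  wl <- suppressWarnings(as.numeric(nm[wl_cols]))
  if (anyNA(wl))
    stop("non-numeric wavelength column header(s): ",
         paste(nm[wl_cols][is.na(wl)], collapse = ", "))
  if (any(diff(wl) <= 0)) stop("wavelength columns are not strictly increasing")
  absorb <- as.matrix(df[wl_cols])
  if (!is.numeric(absorb) || !all(is.finite(absorb))) {
    suppressWarnings(storage.mode(absorb) <- "double")
    bad <- which(!is.finite(absorb), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("malformed numeric cell at data row ", bad[1, 1],
           ", wavelength column '", nm[wl_cols][bad[1, 2]], "'")
  }
  ids <- if (length(id_col)) as.character(df[[id_col]]) else NULL
  targets <- NULL
  if (length(target_cols)) {
    targets <- df[target_cols]
    names(targets) <- sub("^target:", "", nm[target_cols])
  }
  out <- spectra_set(wl, absorb, ids, targets)
  message("read ", n_samples(out), " samples x ", n_channels(out),
          " channels from ", path)
  out
}

#' Write a spectral dataset to a wide CSV file
#'
#' Values are formatted to 12 significant digits, so a read/write/read
#' round trip reproduces the absorbance matrix to formatting precision.
#'
#' @param x a [spectra_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  validate_spectra_set(x)
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  header <- c("sample_id", fmt(x$wavelengths),
              if (!is.null(x$targets)) paste0("target:", names(x$targets)))
  rows <- vapply(seq_len(n_samples(x)), function(i) {
    paste(c(x$sample_ids[i], fmt(x$absorbance[i, ]),
            if (!is.null(x$targets)) fmt(as.numeric(x$targets[i, ]))),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}

#' Randomly split samples into calibration and prediction sets
#'
#' Sampling is without replacement and driven entirely by `seed`, so the same
#' call is reproducible and the same split can be reused across instruments
#' measuring the same physical samples.
#'
#' @param data a [spectra_set].
#' @param n_calibration number of calibration samples; must satisfy
#'   `0 < n_calibration < n_samples(data)`.
#' @param seed integer random seed.
#' @return an object of class `split_index`: list with `calibration_ids`,
#'   `prediction_ids` and `seed`.
#' @examples
#' s <- spectra_set(1:5, matrix(rnorm(40), nrow = 8))
#' sp <- random_split(s, 6, seed = 1)
#' length(sp$calibration_ids)  # 6
#' @export
random_split <- function(data, n_calibration, seed) {
  n <- n_samples(data)
  if (n_calibration <= 0 || n_calibration >= n)
    stop("n_calibration must be strictly between 0 and ", n,
         " (got ", n_calibration, ")")
  cal <- withr::with_seed(as.integer(seed),
                          sample(data$sample_ids, n_calibration))
  structure(list(calibration_ids = sort(cal),
                 prediction_ids = sort(setdiff(data$sample_ids, cal)),
                 seed = as.integer(seed)),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  cat("<split_index> ", length(x$calibration_ids), " calibration / ",
      length(x$prediction_ids), " prediction (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Serialize / restore a split index as JSON
#' @param split a `split_index`.
#' @param path file path.
#' @return `read_split` returns a `split_index`; `write_split` returns `path`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(calibration_ids = as.character(x$calibration_ids),
                 prediction_ids = as.character(x$prediction_ids),
                 seed = as.integer(x$seed)),
            class = "split_index")
}

#' Descriptive statistics of reference values by partition
#'
#' Computes min, max, mean and sample standard deviation (n - 1 denominator)
#' of every target for the calibration set, the prediction set, and the
#' combined total, in the layout conventional for split-summary tables.
#'
#' @param data a [spectra_set] with targets.
#' @param split optional `split_index`; when omitted only the `total` rows
#'   are produced.
#' @return a `data.frame` with columns `target`, `set`, `min`, `max`,
#'   `mean`, `std`.
#' @export
target_statistics <- function(data, split = NULL) {
  if (is.null(data$targets)) stop("spectra_set has no targets")
  one <- function(v, target, set) {
    data.frame(target = target, set = set, min = min(v), max = max(v),
               mean = mean(v), std = stats::sd(v))
  }
  parts <- list(total = data$sample_ids)
  if (!is.null(split))
    parts <- list(calibration = split$calibration_ids,
                  prediction = split$prediction_ids,
                  total = data$sample_ids)
  out <- do.call(rbind, lapply(names(data$targets), function(tg) {
    do.call(rbind, lapply(names(parts), function(p) {
      idx <- match(parts[[p]], data$sample_ids)
      one(data$targets[[tg]][idx], tg, p)
    }))
  }))
  rownames(out) <- NULL
  out
}
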