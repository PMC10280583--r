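#' Construct a spectral dataset
#'
#' A `spectra_set` bundles an absorbance matrix (samples x wavelength
#' channels), its wavelength axis in nanometres, unique sample identifiers,
#' and an optional table of per-sample reference values in percent (e.g.
#' moisture, oil, protein, starch). It is the common currency passed between
#' preprocessing, autoencoder and regression stages.
#'
#' @param wavelengths numeric vector of strictly increasing wavelengths (nm).
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavelength channel. All values must be finite.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `"S1" ... "Sn"`.
#' @param targets optional `data.frame` of reference values, one row per
#'   sample, numeric columns.
#' @return An object of class `spectra_set` with fields `wavelengths`,
#'   `absorbance`, `sample_ids`, `targets`.
#' @examples
#' s <- spectra_set(c(1100, 1102, 1104), matrix(runif(6), nrow = 2))
#' n_samples(s)
#' @export
spectra_set <- function(wavelengths, absorbance, sample_ids = NULL,
                        targets = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  sample_ids <- as.character(sample_ids)
  if (!is.null(targets)) {
    targets <- as.data.frame(targets)
    rownames(targets) <- sample_ids
  }
  obj <- structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         sample_ids = sample_ids, targets = targets),
    class = "spectra_set")
  validate_spectra_set(obj)
  obj
}

validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  p <- ncol(x$absorbance)
  if (length(x$wavelengths) != p)
    stop("wavelength axis length (", length(x$wavelengths),
         ") does not match channel count (", p, ")")
  if (p >= 2 && any(diff(x$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(x$absorbance))) {
    bad <- which(!is.finite(x$absorbance), arr.ind = TRUE)[1, ]
    stop("non-finite absorbance at row ", bad[1], ", column ", bad[2])
  }
  if (anyDuplicated(x$sample_ids))
    stop("sample_ids must be unique")
  if (length(x$sample_ids) != nrow(x$absorbance))
    stop("sample_ids length does not match sample count")
  if (!is.null(x$targets)) {
    if (nrow(x$targets) != nrow(x$absorbance))
      stop("targets must have one row per sample")
    if (!all(vapply(x$targets, is.numeric, logical(1))))
      stop("target columns must be numeric")
  }
  invisible(x)
}

#' @rdname spectra_set
#' @param x a `spectra_set`.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname spectra_set
#' @export
n_channels <- function(x) ncol(x$absorbance)

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", n_samples(x), " samples x ", n_channels(x),
      " channels, ", format(min(x$wavelengths)), "-",
      format(max(x$wavelengths)), " nm\n", sep = "")
  if (!is.null(x$targets))
    cat("  targets: ", paste(names(x$targets), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset a spectra_set by sample identifier
#'
#' @param x a `spectra_set`.
#' @param ids character vector of sample identifiers to keep, in order.
#' @return a `spectra_set` restricted to `ids`.
#' @export
subset_samples <- function(x, ids) {
  idx <- match(ids, x$sample_ids)
  if (anyNA(idx)) stop("unknown sample ids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  spectra_set(x$wavelengths, x$absorbance[idx, , drop = FALSE],
              x$sample_ids[idx],
              if (!is.null(x$targets)) x$targets[idx, , drop = FALSE])
}
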