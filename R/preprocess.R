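#' Scatter-correction and centering preprocessing operators
#'
#' The four operators conventional NIR calibration pipelines combine with
#' PLSR/PCR: standard normal variate (SNV), multiplicative scatter correction
#' (MSC), Savitzky-Golay filtering (SG) and mean centering (MC). SNV and SG
#' are per-spectrum and stateless; MSC and MC learn state (reference
#' spectrum, column means) from the calibration set only and apply it
#' anywhere, so no prediction-set information leaks into the fit.
#'
#' @name preprocess
NULL

#' Standard normal variate transform
#'
#' Centers each spectrum to mean 0 and scales it to unit sample standard
#' deviation (n - 1 denominator), removing per-spectrum multiplicative
#' scatter and offset.
#'
#' @param x numeric vector (a single spectrum) or a matrix of spectra in
#'   rows; at least 2 channels.
#' @return the transformed vector or matrix.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, snv)))
  if (length(x) < 2) stop("snv needs at least 2 channels")
  s <- stats::sd(x)
  if (s < 1e-12) stop("degenerate input: constant spectrum has no SNV transform")
  (x - mean(x)) / s
}

#' Multiplicative scatter correction
#'
#' `msc_fit` learns the reference spectrum (column mean of the calibration
#' matrix). `msc_apply` regresses each spectrum on the reference,
#' `x ~ a + b * reference`, and returns `(x - a) / b`, removing per-spectrum
#' additive offset and multiplicative scatter relative to the reference.
#'
#' @param calibration numeric matrix of calibration spectra (rows).
#' @return `msc_fit`: a `preproc_spec`; `msc_apply`: corrected vector/matrix.
#' @examples
#' X <- matrix(rnorm(50), 5)
#' sp <- msc_fit(X)
#' all.equal(msc_apply(sp, sp$fitted$reference), sp$fitted$reference)
#' @export
msc_fit <- function(calibration) {
  calibration <- as.matrix(calibration)
  if (nrow(calibration) < 1) stop("empty calibration matrix")
  preproc_spec("msc", fitted = list(reference = colMeans(calibration)))
}

#' @rdname msc_fit
#' @param spec a fitted `preproc_spec` from [msc_fit()].
#' @param x spectrum vector or matrix of spectra in rows.
#' @export
msc_apply <- function(spec, x) {
  stopifnot(spec$operator == "msc", !is.null(spec$fitted$reference))
  ref <- spec$fitted$reference
  if (is.matrix(x)) return(t(apply(x, 1, function(r) msc_apply(spec, r))))
  if (length(x) != length(ref))
    stop("channel count ", length(x), " does not match reference ", length(ref))
  b <- stats::cov(ref, x) / stats::var(ref)
  a <- mean(x) - b * mean(ref)
  if (abs(b) < 1e-12)
    stop("degenerate input: spectrum uncorrelated with MSC reference (|b| < 1e-12)")
  (x - a) / b
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Replaces each point by the `deriv`-th derivative of a local least-squares
#' polynomial of order `polyorder` fitted over a centered window of `window`
#' points. Interior points use the classical fixed convolution weights; at
#' the spectrum ends the polynomial is fitted on the one-sided truncated
#' window rather than padding, so no data is fabricated. With a wavelength
#' axis sampled every `delta` nm, derivatives are per nm.
#'
#' @param x numeric vector (spectrum) or matrix of spectra in rows.
#' @param window odd window length >= 3.
#' @param polyorder polynomial order, `< window`.
#' @param deriv derivative order, `>= 0`; must not exceed `polyorder`.
#' @param delta channel spacing used to scale derivatives (default 1).
#' @return filtered vector or matrix, same length as the input.
#' @examples
#' savgol((1:10)^2, window = 5, polyorder = 2)  # reproduced exactly
#' @export
savgol <- function(x, window = 11, polyorder = 2, deriv = 0, delta = 1) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (deriv < 0 || deriv > polyorder) stop("deriv must be in [0, polyorder]")
  if (is.matrix(x))
    return(t(apply(x, 1, savgol, window = window, polyorder = polyorder,
                   deriv = deriv, delta = delta)))
  L <- length(x)
  if (L < window) stop("spectrum shorter than window")
  h <- (window - 1L) / 2L
  # local fit weights for evaluation point at offset 0 within window `offs`
  fit_weights <- function(offs) {
    A <- outer(offs * delta, 0:polyorder, `^`)
    Wrow <- solve(crossprod(A), t(A))[deriv + 1L, ]
    Wrow * factorial(deriv)
  }
  w_int <- fit_weights(-h:h)
  out <- numeric(L)
  interior <- (h + 1L):(L - h)
  # interior: single convolution with the classical kernel
  for (j in seq_len(window))
    out[interior] <- out[interior] + w_int[j] * x[interior + j - h - 1L]
  for (i in seq_len(h)) {                      # truncated one-sided windows
    offs <- (1L - i):h                         # left edge
    out[i] <- sum(fit_weights(offs) * x[i + offs])
    k <- L - h + i                             # right edge
    offs <- (-h):(L - k)
    out[k] <- sum(fit_weights(offs) * x[k + offs])
  }
  out
}

#' Mean centering
#'
#' `mean_center_fit` stores the calibration column means;
#' `mean_center_apply` subtracts them from any matrix with the same channel
#' count, so calibration columns become zero-mean and prediction columns are
#' expressed as deviations from the calibration mean spectrum.
#'
#' @param calibration numeric matrix of calibration spectra (rows).
#' @return `mean_center_fit`: a `preproc_spec`; `mean_center_apply`: matrix.
#' @export
mean_center_fit <- function(calibration) {
  calibration <- as.matrix(calibration)
  if (nrow(calibration) < 1) stop("empty calibration matrix")
  preproc_spec("mean_center", fitted = list(means = colMeans(calibration)))
}

#' @rdname mean_center_fit
#' @param spec a fitted `preproc_spec` from [mean_center_fit()].
#' @param x matrix of spectra in rows (or a single spectrum vector).
#' @export
mean_center_apply <- function(spec, x) {
  stopifnot(spec$operator == "mean_center", !is.null(spec$fitted$means))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(spec$fitted$means))
    stop("channel count ", ncol(x), " does not match fitted means ",
         length(spec$fitted$means))
  out <- sweep(x, 2, spec$fitted$means)
  if (vec) out[1, ] else out
}

#' Declarative preprocessing specification
#'
#' A `preproc_spec` names one operator (`none`, `snv`, `msc`, `savgol`,
#' `mean_center`), its parameters, and — for MSC and mean centering — the
#' state fitted on calibration data. [preprocess_fit()] fits any operator on
#' a calibration matrix; [preprocess_apply()] applies a fitted spec to new
#' spectra.
#'
#' @param operator operator name.
#' @param params named list of operator parameters (savgol: `window`,
#'   `polyorder`, `deriv`, `delta`).
#' @param fitted named list of fitted state, or `NULL` before fitting.
#' @return an object of class `preproc_spec`.
#' @export
preproc_spec <- function(operator = c("none", "snv", "msc", "savgol",
                                      "mean_center"),
                         params = list(), fitted = NULL) {
  operator <- match.arg(operator)
  if (operator == "savgol") {
    params <- utils::modifyList(
      list(window = 11L, polyorder = 2L, deriv = 0L, delta = 1), params)
    if (params$window %% 2 == 0 || params$polyorder >= params$window)
      stop("savgol window must be odd and greater than polyorder")
  }
  structure(list(operator = operator, params = params, fitted = fitted),
            class = "preproc_spec")
}

#' @rdname preproc_spec
#' @param calibration calibration absorbance matrix (samples in rows).
#' @export
preprocess_fit <- function(operator, calibration, params = list()) {
  switch(operator,
         none = preproc_spec("none"),
         snv = preproc_spec("snv"),
         savgol = preproc_spec("savgol", params = params),
         msc = msc_fit(calibration),
         mean_center = mean_center_fit(calibration),
         stop("unknown operator: ", operator))
}

#' @rdname preproc_spec
#' @param spec a `preproc_spec`.
#' @param x matrix of spectra in rows.
#' @export
preprocess_apply <- function(spec, x) {
  stopifnot(inherits(spec, "preproc_spec"))
  switch(spec$operator,
         none = x,
         snv = snv(x),
         savgol = do.call(savgol, c(list(x), spec$params)),
         msc = msc_apply(spec, x),
         mean_center = mean_center_apply(spec, x))
}

#' @export
print.preproc_spec <- function(x, ...) {
  cat("<preproc_spec> ", x$operator,
      if (length(x$params)) paste0(" (",
        paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
        ")"),
      if (!is.null(x$fitted)) " [fitted]", "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a preprocessing spec as JSON
#' @param spec a `preproc_spec`.
#' @param path file path.
#' @return `read_preproc_spec` returns a `preproc_spec`.
#' @export
write_preproc_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_preproc_spec
#' @export
read_preproc_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  preproc_spec(x$operator, as.list(x$params),
               if (!is.null(x$fitted) && length(x$fitted))
                 lapply(x$fitted, as.numeric))
}
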