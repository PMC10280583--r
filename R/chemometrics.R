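#' Fitted linear calibration model
#'
#' All three regression families (`mlr`, `plsr`, `pcr`) reduce to the same
#' affine predictor `y_hat = X %*% coefficients + intercept` in the input
#' feature space; the object additionally records the component count and
#' centering vectors for PLSR/PCR, and the preprocessing spec the model was
#' trained behind so `predict()` can be applied to raw spectra.
#'
#' @param family one of `"mlr"`, `"plsr"`, `"pcr"`.
#' @param coefficients coefficient vector in input-feature space.
#' @param intercept scalar intercept.
#' @param n_components component count (PLSR/PCR) or `NA` for MLR.
#' @param x_center,y_center centering vectors fitted on calibration.
#' @param preprocessing optional [preproc_spec()] applied before prediction.
#' @param extra named list of family-specific extras (e.g. PLS scores).
#' @return object of class `regression_model`.
#' @export
regression_model <- function(family, coefficients, intercept,
                             n_components = NA_integer_, x_center = NULL,
                             y_center = NULL, preprocessing = NULL,
                             extra = list()) {
  structure(list(family = family, coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 n_components = n_components, x_center = x_center,
                 y_center = y_center, preprocessing = preprocessing,
                 extra = extra),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat("<regression_model> ", x$family,
      if (!is.na(x$n_components)) paste0(" (", x$n_components, " components)"),
      ", ", length(x$coefficients), " features\n", sep = "")
  invisible(x)
}

#' @export
predict.regression_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$preprocessing))
    X <- preprocess_apply(object$preprocessing, X)
  if (ncol(X) != length(object$coefficients))
    stop("feature count mismatch: ", ncol(X), " vs ",
         length(object$coefficients))
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' Multiple linear regression on latent variables
#'
#' Ordinary least squares with intercept, the second stage of the proposed
#' method: the autoencoder's latent variables are few enough (32 versus 60
#' calibration samples) that OLS is well posed, which it is not on the raw
#' 700-channel spectra.
#'
#' @param latents numeric matrix (samples x features), e.g. from [encode()].
#' @param targets numeric vector of reference values.
#' @param preprocessing optional [preproc_spec()] recorded on the model.
#' @return a [regression_model()] of family `"mlr"`.
#' @export
fit_mlr <- function(latents, targets, preprocessing = NULL) {
  X <- as.matrix(latents)
  y <- as.numeric(targets)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X))
    stop("MLR needs more samples (", nrow(X), ") than features (", ncol(X),
         "); reduce dimensionality first")
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrD, y)
  regression_model("mlr", beta[-1], beta[1], preprocessing = preprocessing)
}

#' Partial least squares regression (NIPALS, single response)
#'
#' X and y are centered by their calibration means; components are extracted
#' by NIPALS with deflation of both blocks, so scores of distinct components
#' are orthogonal. The fitted model is returned as the equivalent affine
#' predictor in the original feature space.
#'
#' @param X numeric matrix (samples x features).
#' @param y numeric response vector.
#' @param n_components number of latent components,
#'   `1 <= n_components <= min(n_samples - 1, n_features)`.
#' @param preprocessing optional [preproc_spec()] recorded on the model.
#' @return a [regression_model()] of family `"plsr"`; `extra$scores` holds
#'   the calibration score matrix.
#' @export
fit_plsr <- function(X, y, n_components, preprocessing = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components must be in [1, ", min(n - 1, p), "]")
  if (stats::sd(y) < 1e-12) stop("zero-variance response")
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_center
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  for (h in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      warning("residual X'y vanished at component ", h,
              "; truncating to ", h - 1L, " components")
      W <- W[, seq_len(h - 1L), drop = FALSE]
      P <- P[, seq_len(h - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(h - 1L), drop = FALSE]
      q <- q[seq_len(h - 1L)]
      n_components <- h - 1L
      break
    }
    w <- w / nw
    tt <- as.numeric(E %*% w)
    tt2 <- sum(tt^2)
    p_h <- as.numeric(crossprod(E, tt)) / tt2
    q_h <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, p_h)
    f <- f - q_h * tt
    W[, h] <- w
    P[, h] <- p_h
    Tm[, h] <- tt
    q[h] <- q_h
  }
  B <- W %*% solve(crossprod(P, W), q)
  regression_model("plsr", B, y_center - sum(x_center * B),
                   n_components = n_components, x_center = x_center,
                   y_center = y_center, preprocessing = preprocessing,
                   extra = list(scores = Tm))
}

#' Principal component regression
#'
#' PCA of the centered X by singular value decomposition (components ordered
#' by decreasing singular value), then OLS of the centered response on the
#' leading scores; returned as the equivalent affine predictor.
#'
#' @inheritParams fit_plsr
#' @return a [regression_model()] of family `"pcr"`; `extra$scores` holds
#'   the calibration score matrix.
#' @export
fit_pcr <- function(X, y, n_components, preprocessing = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n_components < 1 || n_components > min(n - 1, ncol(X)))
    stop("n_components must be in [1, ", min(n - 1, ncol(X)), "]")
  if (stats::sd(y) < 1e-12) stop("zero-variance response")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  gamma <- qr.coef(qr(scores), y - y_center)
  B <- sv$v %*% gamma
  regression_model("pcr", B, y_center - sum(x_center * B),
                   n_components = n_components, x_center = x_center,
                   y_center = y_center, preprocessing = preprocessing,
                   extra = list(scores = scores,
                                singular_values = sv$d))
}

#' Cross-validated component-count selection for PLSR/PCR
#'
#' Samples are assigned to `folds` shuffled folds from a stated seed; for
#' every component count `k = 1..k_max` the mean held-out RMSE over folds is
#' computed and the count minimising it is selected, with ties broken toward
#' fewer components. The fold assignment is shared across `k` and can be
#' reused across families, so comparisons are paired.
#'
#' @param X numeric matrix (samples x features), already preprocessed.
#' @param y numeric response vector.
#' @param family `"plsr"` or `"pcr"`.
#' @param k_max largest component count tried (clipped, with a warning, when
#'   it reaches the smallest training-fold size).
#' @param folds number of CV folds.
#' @param seed integer seed for the fold shuffle.
#' @return object of class `cv_result`: list with `cv_rmse` (named numeric,
#'   one entry per k), `selected_count`, `family`, `seed`.
#' @export
select_components_cv <- function(X, y, family = c("plsr", "pcr"),
                                 k_max = 10L, folds = 5L, seed = 1L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < folds) stop("need at least as many samples as folds")
  if (stats::sd(y) < 1e-12) stop("zero-variance response")
  assign <- withr::with_seed(as.integer(seed),
                             sample(rep(seq_len(folds), length.out = n)))
  min_train <- min(vapply(seq_len(folds),
                          function(f) sum(assign != f), integer(1)))
  limit <- min(min_train - 1L, ncol(X))
  if (k_max > limit) {
    warning("k_max clipped from ", k_max, " to ", limit,
            " by the smallest training fold")
    k_max <- limit
  }
  fitter <- if (family == "plsr") fit_plsr else fit_pcr
  cv_rmse <- vapply(seq_len(k_max), function(k) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- assign != f
      m <- fitter(X[tr, , drop = FALSE], y[tr], k)
      rmse(y[!tr], predict(m, X[!tr, , drop = FALSE]))
    }, numeric(1)))
  }, numeric(1))
  names(cv_rmse) <- seq_len(k_max)
  structure(list(cv_rmse = cv_rmse,
                 selected_count = as.integer(which.min(cv_rmse)),
                 family = family, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$family, ": selected ", x$selected_count,
      " components (CV RMSE ", format(min(x$cv_rmse), digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' Serialize / restore a regression model as JSON
#' @param model a `regression_model`.
#' @param path file path.
#' @return `read_regression_model` returns a `regression_model`.
#' @export
write_regression_model <- function(model, path) {
  out <- unclass(model)
  out$extra <- NULL
  out$preprocessing <- if (!is.null(model$preprocessing))
    unclass(model$preprocessing)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_regression_model
#' @export
read_regression_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pre <- if (!is.null(x$preprocessing))
    preproc_spec(x$preprocessing$operator, as.list(x$preprocessing$params),
                 if (length(x$preprocessing$fitted))
                   lapply(x$preprocessing$fitted, as.numeric))
  regression_model(x$family, x$coefficients, x$intercept,
                   n_components = if (is.null(x$n_components)) NA_integer_
                                  else as.integer(x$n_components),
                   x_center = if (!is.null(x$x_center)) as.numeric(x$x_center),
                   y_center = if (!is.null(x$y_center)) as.numeric(x$y_center),
                   preprocessing = pre)
}
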