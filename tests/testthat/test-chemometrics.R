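test_that("MLR recovers exact linear relations and flags degeneracy", {
  X <- matrix(c(1, 0, 0, 0, 1, 0), 3)
  y <- 2 * X[, 1] - 1 * X[, 2] + 5
  m <- fit_mlr(X, y)
  expect_equal(m$coefficients, c(2, -1), ignore_attr = TRUE)
  expect_equal(m$intercept, 5, ignore_attr = TRUE)
  expect_equal(predict(m, X), y)
  # n == p is refused
  expect_error(fit_mlr(matrix(rnorm(9), 3), rnorm(3)), "more samples")
  # collinear columns are named
  Xc <- cbind(a = rnorm(10), b = rnorm(10))
  Xc <- cbind(Xc, c = Xc[, "a"] + Xc[, "b"])
  expect_error(fit_mlr(Xc, rnorm(10)), "collinear.*c")
})

test_that("MLR residuals are orthogonal to every column and the intercept", {
  set.seed(11)
  X <- matrix(rnorm(60 * 32), 60)
  y <- X %*% rnorm(32) + rnorm(60, 0, 0.5)
  m <- fit_mlr(X, y)
  resid <- as.numeric(y) - predict(m, X)
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)
  expect_lt(abs(sum(resid)), 1e-8)
})

test_that("PLSR with all components equals OLS; one component recovers a single factor", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(10, 0, 0.1)
  pls <- fit_plsr(X, y, 4)
  ols <- fit_mlr(X, y)
  expect_equal(predict(pls, X), predict(ols, X), tolerance = 1e-8)
  # y proportional to one column of a centered orthogonal design: a single
  # component captures it exactly (centering leaves such columns unchanged)
  Xo <- qr.Q(qr(scale(X, scale = FALSE)))
  y1 <- 3 * Xo[, 1]
  m1 <- fit_plsr(Xo, y1, 1)
  expect_lt(rmse(y1, predict(m1, Xo)), 1e-10)
  expect_error(fit_plsr(X, rep(1, 10), 2), "zero-variance")
  expect_error(fit_plsr(X, y, 11), "n_components")
})

test_that("PLSR scores of distinct components are orthogonal", {
  cal <- calibration_set()
  m <- fit_plsr(cal$absorbance, cal$targets$protein, 10)
  G <- crossprod(m$extra$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("PLSR agrees with the mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(13)
  X <- matrix(rnorm(30 * 12), 30,
              dimnames = list(NULL, paste0("V", 1:12)))
  y <- X %*% rnorm(12) + rnorm(30)
  ours <- fit_plsr(X, y, 3)
  theirs <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                          scale = FALSE)
  ref <- predict(theirs, X)$predict[, 1, 3]
  expect_equal(predict(ours, X), as.numeric(ref), tolerance = 1e-6)
})

test_that("PCR equals OLS at full rank and orders components by variance", {
  set.seed(14)
  X <- matrix(rnorm(48), 12, 4)
  y <- X %*% c(2, 1, -1, 0.5) + rnorm(12, 0, 0.1)
  pcr <- fit_pcr(X, y, 4)
  ols <- fit_mlr(X, y)
  expect_equal(predict(pcr, X), predict(ols, X), tolerance = 1e-8)
  # dominant-direction fixture: one component captures > 99% of X variance
  t1 <- rnorm(50)
  Xd <- outer(t1, c(5, 4, 3)) + matrix(rnorm(150, 0, 0.05), 50)
  m1 <- fit_pcr(Xd, t1, 1)
  sv <- m1$extra$singular_values
  expect_gt(sv[1]^2 / sum(sv^2), 0.99)
  # scores are uncorrelated
  m3 <- fit_pcr(Xd, t1, 3)
  G <- crossprod(m3$extra$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("the three families coincide on a full-rank design with all components", {
  set.seed(15)
  X <- matrix(rnorm(60), 15, 4)
  y <- X %*% c(1, 2, 3, 4) + rnorm(15, 0, 0.2)
  Xnew <- matrix(rnorm(20), 5, 4)
  p_mlr <- predict(fit_mlr(X, y), Xnew)
  p_pls <- predict(fit_plsr(X, y, 4), Xnew)
  p_pcr <- predict(fit_pcr(X, y, 4), Xnew)
  expect_lt(max(abs(p_mlr - p_pls)), 1e-6)
  expect_lt(max(abs(p_mlr - p_pcr)), 1e-6)
})

test_that("prediction is exactly affine in the input features", {
  set.seed(16)
  X <- matrix(rnorm(80), 20, 4)
  y <- X %*% c(1, -1, 2, 0) + rnorm(20, 0, 0.1)
  m <- fit_plsr(X, y, 3)
  x0 <- colMeans(X)
  d <- rnorm(4)
  f <- function(t) predict(m, matrix(x0 + t * d, 1))
  expect_equal(f(2) - f(0), 2 * (f(1) - f(0)), tolerance = 1e-10)
})

test_that("CV component selection concentrates at the true factor count", {
  hits <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    Tm <- matrix(rnorm(40 * 3), 40)
    L <- matrix(rnorm(3 * 20), 3)
    X <- Tm %*% L + matrix(rnorm(40 * 20, 0, 0.05), 40)
    y <- Tm %*% c(2, -1, 1) + rnorm(40, 0, 0.1)
    cv <- select_components_cv(X, y, "plsr", k_max = 10, folds = 5, seed = s)
    hits <- hits + (cv$selected_count == 3)
  }
  expect_gte(hits, 3)
})

test_that("CV selection is deterministic and validates inputs", {
  cal <- calibration_set()
  cv1 <- select_components_cv(cal$absorbance, cal$targets$oil, "plsr",
                              seed = 4)
  cv2 <- select_components_cv(cal$absorbance, cal$targets$oil, "plsr",
                              seed = 4)
  expect_identical(cv1, cv2)
  expect_equal(cv1$selected_count,
               as.integer(which.min(cv1$cv_rmse)))
  expect_error(select_components_cv(cal$absorbance, rep(1, 60), "plsr"),
               "zero-variance")
  # k_max clipped by the smallest training fold
  X <- matrix(rnorm(8 * 20), 8)
  y <- rnorm(8)
  expect_warning(cv <- select_components_cv(X, y, "pcr", k_max = 10,
                                            folds = 4, seed = 1),
                 "clipped")
  expect_lte(length(cv$cv_rmse), 5)
})

test_that("regression models serialize to JSON and back", {
  cal <- calibration_set()
  spec <- preprocess_fit("snv", cal$absorbance)
  X <- preprocess_apply(spec, cal$absorbance)
  m <- fit_plsr(X, cal$targets$starch, 4, preprocessing = spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_regression_model(m, path)
  m2 <- read_regression_model(path)
  # stored preprocessing is applied automatically to raw spectra
  pr <- prediction_set()
  expect_equal(predict(m2, pr$absorbance),
               as.numeric(preprocess_apply(spec, pr$absorbance) %*%
                            m$coefficients + m$intercept),
               tolerance = 1e-10)
  expect_equal(m2$n_components, 4L)
})
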