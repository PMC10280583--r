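test_that("snv centers and scales each spectrum", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- runif(700)
  expect_lt(abs(mean(snv(x))), 1e-12)
  expect_lt(abs(sd(snv(x)) - 1), 1e-12)
  # affine invariance and idempotence
  expect_equal(snv(3.7 * x + 12), snv(x))
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-12)
  expect_error(snv(rep(2, 10)), "degenerate")
  expect_error(snv(5), "at least 2")
  # matrix form operates per row
  X <- rbind(x, 2 * x + 1)
  expect_equal(unname(snv(X)[2, ]), snv(x))
})

test_that("msc removes affine scatter relative to the calibration reference", {
  set.seed(2)
  X <- matrix(runif(200, 0.2, 1), 10)
  spec <- msc_fit(X)
  ref <- spec$fitted$reference
  expect_equal(ref, colMeans(X))
  expect_equal(msc_apply(spec, ref), ref)            # fixed point
  expect_equal(msc_apply(spec, 2 * ref + 3), ref)    # exact affine removal
  expect_equal(msc_apply(spec, 0.3 * ref - 1), ref)
  expect_error(msc_apply(spec, rnorm(20) * 1e-15 + mean(ref)), "degenerate")
})

test_that("msc reduces between-replicate variance of scatter-distorted spectra", {
  base <- default_library()$curves %*% c(10, 3.5, 8.7, 64.7)
  set.seed(3)
  reps <- t(sapply(1:12, function(i)
    exp(rnorm(1, 0, 0.1)) * as.numeric(base) + rnorm(1, 0, 0.02)))
  spec <- msc_fit(reps)
  corrected <- msc_apply(spec, reps)
  expect_lt(mean(apply(corrected, 2, var)), mean(apply(reps, 2, var)))
})

test_that("savgol reproduces polynomials and their derivatives", {
  x <- (1:30)^2
  expect_equal(savgol(x, window = 5, polyorder = 2), as.numeric(x))
  ramp <- 3 * (1:30)
  expect_equal(savgol(ramp, window = 5, polyorder = 2, deriv = 1),
               rep(3, 30))
  const <- rep(1.7, 40)
  expect_equal(savgol(const, window = 11, polyorder = 2), const)
  expect_error(savgol(x, window = 4), "odd")
  expect_error(savgol(x, window = 5, polyorder = 5), "smaller than window")
  expect_error(savgol(1:3, window = 5), "shorter")
})

test_that("savgol(5,2) interior equals the published convolution kernel", {
  set.seed(4)
  x <- rnorm(50)
  sg <- savgol(x, window = 5, polyorder = 2)
  kern <- c(-3, 12, 17, 12, -3) / 35
  direct <- sapply(3:48, function(i) sum(kern * x[(i - 2):(i + 2)]))
  expect_equal(sg[3:48], direct, tolerance = 1e-12)
  # independent oracle: explicit local least-squares fit at each point
  oracle <- sapply(3:48, function(i) {
    fit <- lm(y ~ poly(t, 2, raw = TRUE),
              data = data.frame(t = -2:2, y = x[(i - 2):(i + 2)]))
    unname(fit$fitted.values[3])
  })
  expect_equal(sg[3:48], oracle, tolerance = 1e-10)
})

test_that("savgol interior agrees with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(5)
  x <- rnorm(80)
  ours <- savgol(x, window = 11, polyorder = 2)
  theirs <- signal::sgolayfilt(x, p = 2, n = 11)
  expect_equal(ours[6:75], theirs[6:75], tolerance = 1e-10)
})

test_that("mean centering subtracts calibration column means", {
  cal <- matrix(c(1, 3, 2, 4), 2)
  spec <- mean_center_fit(cal)
  expect_equal(spec$fitted$means, c(2, 3))
  expect_equal(mean_center_apply(spec, cal), matrix(c(-1, 1, -1, 1), 2))
  expect_equal(mean_center_apply(spec, c(2, 3)), c(0, 0))
  expect_error(mean_center_apply(spec, matrix(1, 1, 3)), "does not match")
  # prediction column means shift by (pred_mean - cal_mean)
  set.seed(6)
  pred <- matrix(rnorm(40, 5), 10, 4)
  cal2 <- matrix(rnorm(40), 10, 4)
  spec2 <- mean_center_fit(cal2)
  expect_equal(colMeans(mean_center_apply(spec2, pred)),
               colMeans(pred) - colMeans(cal2))
})

test_that("preprocess_fit/apply dispatch and serialization round-trip", {
  cal <- matrix(runif(60, 0.2, 1), 6)
  for (op in c("none", "snv", "msc", "savgol", "mean_center")) {
    spec <- preprocess_fit(op, cal, params = if (op == "savgol")
      list(window = 5) else list())
    out <- preprocess_apply(spec, cal)
    expect_equal(dim(out), dim(cal))
    path <- withr::local_tempfile(fileext = ".json")
    write_preproc_spec(spec, path)
    spec2 <- read_preproc_spec(path)
    expect_equal(preprocess_apply(spec2, cal), out, tolerance = 1e-12)
  }
  expect_error(preproc_spec("savgol", params = list(window = 4)), "odd")
})
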