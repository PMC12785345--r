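test_that("SNV normalizes rows and flags constant rows", {
  expect_equal(snv(matrix(1:3, 1)), matrix(c(-1, 0, 1), 1))
  expect_error(snv(rbind(1:3, c(5, 5, 5))), "row 2")
  set.seed(11)
  X <- matrix(rnorm(200), 10)
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
})

test_that("MSC inverts per-spectrum affine distortions", {
  set.seed(12)
  ref <- msc_fit(matrix(rnorm(60), 3))
  # x = 1 + 2 * ref recovers ref exactly; x = ref is a fixed point
  X <- rbind(1 + 2 * ref, ref)
  expect_equal(msc_apply(X, ref), rbind(ref, ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  # random 3-point row: (a, b) match the closed-form two-parameter OLS
  ref3 <- c(0.2, 0.5, 0.9)
  x <- c(1.3, 0.7, 2.1)
  ab <- ols2(x, ref3)
  expect_equal(msc_apply(matrix(x, 1), ref3)[1, ],
               (x - ab["a"]) / ab["b"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(msc_apply(matrix(rep(mean(ref), 20), 1), ref), "degenerate")
  expect_error(msc_fit(matrix(0, 0, 5)), "empty")
})

test_that("Savitzky-Golay coefficients match the classical quadratic filter", {
  expect_equal(savgol_coef(5, 2, 0), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  expect_error(savgol_coef(4, 2, 0), "odd")
  expect_error(savgol_coef(5, 5, 0), "exceed")
})

test_that("SG smoothing reproduces polynomials everywhere, incl. edges", {
  i <- 1:60
  quad <- rbind(3 + 0.5 * i - 0.02 * i^2)
  expect_equal(savgol(quad, 11, 2, 0), quad, tolerance = 1e-9)
  # first derivative of a polynomial, scaled by an arbitrary spacing
  delta <- -2.5
  d1 <- savgol(quad, 11, 2, 1, delta = delta)
  expect_equal(d1, rbind((0.5 - 0.04 * i) / delta), tolerance = 1e-9)
  d2 <- savgol(quad, 11, 2, 2, delta = delta)
  expect_equal(d2, rbind(rep(-0.04 / delta^2, 60)), tolerance = 1e-9)
  expect_equal(savgol(rbind(rep(7, 30)), 7, 2, 1), rbind(rep(0, 30)))
  expect_error(savgol(quad, 61, 2, 0), "exceeds")
})

test_that("finite-difference derivatives match analytic polynomials", {
  i <- 1:40
  delta <- 3.856
  lin <- rbind(2 + 0.7 * (i * delta))      # slope 0.7 per unit of nu
  expect_equal(spectral_derivative(lin, 1, delta), rbind(rep(0.7, 40)),
               tolerance = 1e-9)
  expect_equal(spectral_derivative(rbind(rep(1, 40)), 2, delta),
               rbind(rep(0, 40)))
  quad <- rbind(0.3 * (i * delta)^2)
  d2 <- spectral_derivative(quad, 2, delta)
  expect_equal(d2, rbind(rep(0.6, 40)), tolerance = 1e-8)
  expect_error(spectral_derivative(matrix(1, 1, 2), 2), "at least 3")
})

test_that("the registry holds exactly the 15 screened pipelines", {
  reg <- pipeline_registry()
  expect_length(reg, 15)
  expect_setequal(names(reg), c(
    "RAW", "1st Der", "1st Der + SG", "2nd Der", "2nd Der + SG",
    "MSC", "MSC + 1st Der", "MSC + 1st Der + SG", "MSC + 2nd Der",
    "MSC + 2nd Der + SG", "SNV", "SNV + 1st Der", "SNV + 1st Der + SG",
    "SNV + 2nd Der", "SNV + 2nd Der + SG"))
  expect_error(preprocess_pipeline("wavelet"), "unknown pipeline")
})

test_that("apply_pipeline delegates, keeps RAW identity and is hygienic", {
  set.seed(13)
  cal <- matrix(rnorm(80, 1, 0.2), 4)
  new <- matrix(rnorm(40, 1, 0.2), 2)
  raw <- apply_pipeline(preprocess_pipeline("RAW"), cal, list(new))
  expect_identical(raw$calibration, cal)
  expect_identical(raw$others[[1]], new)
  expect_equal(apply_pipeline(preprocess_pipeline("SNV"),
                              matrix(1:3, 1))$calibration,
               matrix(c(-1, 0, 1), 1))
  # MSC state must come from fit_pipeline, never from the new data
  expect_error(transform_pipeline(preprocess_pipeline("MSC + 1st Der"), new),
               "not fitted")
  fitted <- fit_pipeline(preprocess_pipeline("MSC"), cal)
  out1 <- transform_pipeline(fitted, new)
  fitted2 <- fit_pipeline(preprocess_pipeline("MSC"), cal * 2)  # other cal
  expect_false(isTRUE(all.equal(out1, transform_pipeline(fitted2, new))))
})

test_that("SNV and MSC pipelines are invariant to per-spectrum affine maps", {
  set.seed(14)
  cal <- matrix(rnorm(300, 1, 0.3), 10)
  b <- runif(10, 0.5, 2); a <- runif(10, -0.3, 0.3)
  distorted <- cal * b + a
  for (nm in c("SNV", "SNV + 1st Der", "MSC + 1st Der", "MSC + 2nd Der + SG")) {
    pl <- fit_pipeline(preprocess_pipeline(nm), cal, delta = 2)
    expect_equal(transform_pipeline(pl, distorted),
                 transform_pipeline(pl, cal), tolerance = 1e-8)
  }
})
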