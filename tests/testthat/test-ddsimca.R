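test_that("score and orthogonal distances match a hand-built 2-D projection", {
  # 3 samples, 2 variables, A = 1: project on PC1, residual is orthogonal
  X <- rbind(c(0, 0), c(2, 1), c(4, 2))    # collinear + one off-axis point
  X[2, 2] <- 1.5
  pca <- pca_fit(X, A = 1)
  d <- dds_distances(pca, X, 1)
  # oracle: explicit centring, unit direction, projection and residual
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  dir <- eigen(cov(X))$vectors[, 1]
  t1 <- Xc %*% dir
  lam <- as.vector(var(t1))
  expect_equal(d$h, as.vector(t1^2 / lam), tolerance = 1e-10)
  expect_equal(d$v, rowSums((Xc - t1 %*% t(dir))^2), tolerance = 1e-10)
  # the calibration mean has h = v = 0; in-subspace points have v = 0
  d_mu <- dds_distances(pca, rbind(mu), 1)
  expect_equal(d_mu$h, 0, tolerance = 1e-20)
  expect_equal(d_mu$v, 0, tolerance = 1e-20)
  in_plane <- rbind(mu + 3 * dir)
  expect_lt(dds_distances(pca, in_plane, 1)$v, 1e-20)
})

test_that("moment-based DoF estimation follows the stated arithmetic", {
  # mean 2, variance 4 -> N = 2
  d1 <- c(2 - sqrt(2), 2 + sqrt(2))
  expect_equal(var(d1), 4)
  s <- estimate_dof(d1)
  expect_equal(s$d0, 2)
  expect_equal(s$N, 2L)
  # mean 3, variance 1 -> N = 18
  d2 <- c(3 - sqrt(0.5), 3 + sqrt(0.5))
  expect_equal(var(d2), 1)
  expect_equal(estimate_dof(d2)$N, 18L)
  # degenerate constant distances hit the upper clip
  expect_equal(estimate_dof(rep(5, 10))$N, 250)
  expect_error(estimate_dof(rep(0, 10)), "degenerate")
  expect_error(estimate_dof(numeric(0)), "empty")
})

test_that("DoF estimator recovers the true N from large chi-squared samples", {
  for (N in c(1, 5, 20)) {
    d <- with(list(), {
      set.seed(1000 + N)
      (2.5 / N) * rchisq(50000, N)
    })
    est <- estimate_dof(d)
    expect_equal(est$N, N)
    expect_equal(est$d0, 2.5, tolerance = 0.05)
  }
})

test_that("fitting enforces the one-class contract and threshold structure", {
  ds <- small_dataset()
  G <- ds$absorbance[ds$label == "genuine", ]
  expect_error(dds_fit(ds$absorbance, 3, labels = ds$label), "one-class")
  m <- dds_fit(G, n_pc = 3)
  expect_gt(m$h0, 0); expect_gt(m$v0, 0)
  expect_true(m$N_h >= 1 && m$N_h <= 250)
  expect_gte(m$c_out, m$c_crit)
  expect_equal(m$c_crit, qchisq(0.99, m$N_h + m$N_v))
  # shrinking alpha enlarges the acceptance region
  m2 <- dds_fit(G, n_pc = 3, alpha = 0.001)
  expect_gt(m2$c_crit, m$c_crit)
  # gamma -> 0 pushes the outlier cutoff out monotonically
  m3 <- dds_fit(G, n_pc = 3, gamma = 1e-9)
  expect_gt(m3$c_out, m$c_out)
  expect_error(dds_fit(G[1:3, ], n_pc = 3), "smaller than")
})

test_that("prediction accepts the centre, rejects gross deviants, stays deterministic", {
  ds <- small_dataset()
  G <- ds$absorbance[ds$label == "genuine", ]
  m <- dds_fit(G, n_pc = 3)
  centre <- rbind(m$pca$mean)
  expect_equal(predict(m, centre)$verdict, "genuine")
  expect_false(predict(m, centre * 100)$verdict == "genuine")
  p1 <- predict(m, ds$absorbance)
  p2 <- predict(m, ds$absorbance)
  expect_identical(p1, p2)
  expect_error(predict(m, ds$absorbance[, 1:10]), "grid mismatch")
})

test_that("model parameters depend on the genuine training spectra only", {
  ds <- small_dataset()
  G <- ds$absorbance[ds$label == "genuine", ]
  m1 <- dds_fit(G, n_pc = 4)
  m2 <- dds_fit(G, n_pc = 4)
  expect_identical(m1, m2)
  # scale equivariance: scaling everything leaves verdicts unchanged
  k <- 3.7
  mk <- dds_fit(G * k, n_pc = 4)
  expect_identical(predict(mk, ds$absorbance * k)$verdict,
                   predict(m1, ds$absorbance)$verdict)
})

test_that("acceptance-region coverage is calibrated for chi-squared distances", {
  # distances simulated exactly chi-squared with known DoF: the accepted
  # fraction converges to 1 - alpha
  set.seed(41)
  n <- 10000
  N_h <- 4; N_v <- 11; h0 <- 2; v0 <- 0.3; alpha <- 0.05
  h <- (h0 / N_h) * rchisq(n, N_h)
  v <- (v0 / N_v) * rchisq(n, N_v)
  cc <- N_h * h / h0 + N_v * v / v0
  accepted <- mean(cc <= qchisq(1 - alpha, N_h + N_v))
  expect_lt(abs(accepted - (1 - alpha)), 3 * sqrt(alpha * (1 - alpha) / n))
})

test_that("evaluation arithmetic and component selection behave as specified", {
  verdicts <- c(rep("genuine", 9), "adulterated",            # truth: genuine
                rep("adulterated", 19), "genuine")           # truth: adulterated
  labels <- c(rep("genuine", 10), rep("adulterated", 20))
  r <- dds_evaluate(verdicts, labels)
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$specificity, 0.95)
  expect_equal(r$accuracy, 28 / 30, tolerance = 1e-12)
  all_ok <- dds_evaluate(labels, labels)
  expect_equal(all_ok$accuracy, 1)
  none <- dds_evaluate(rep("adulterated", 10), rep("genuine", 10))
  expect_equal(none$sensitivity, 0)
  expect_error(dds_evaluate(character(0), character(0)), "empty")
  # selection refuses a single-class validation set
  ds <- small_dataset()
  G <- ds$absorbance[ds$label == "genuine", ]
  expect_error(dds_select_n_pc(G[1:10, ], G[11:14, ], rep("genuine", 4)),
               "both genuine and adulterated")
})

test_that("JSON serialization round-trips a fitted model", {
  ds <- small_dataset()
  G <- ds$absorbance[ds$label == "genuine", ]
  m <- dds_fit(G, n_pc = 3)
  path <- withr::local_tempfile(fileext = ".json")
  dds_to_json(m, path)
  back <- dds_from_json(path)
  expect_equal(back$c_crit, m$c_crit)
  expect_identical(predict(back, ds$absorbance)$verdict,
                   predict(m, ds$absorbance)$verdict)
})
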