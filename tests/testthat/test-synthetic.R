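test_that("endmember construction is deterministic and well separated", {
  ems1 <- make_endmembers(0)
  ems2 <- make_endmembers(0)
  expect_identical(ems1, ems2)
  expect_named(ems1, c("DKM", "DL", "DH", "DKML", "bamboo", "corn"),
               ignore.order = TRUE)
  grid <- wn_grid()
  for (em in ems1) {
    # every class keeps a band in the O-H first-overtone region
    expect_true(any(em$bands$center >= 6600 & em$bands$center <= 7075))
    expect_true(all(evaluate_endmember(em, grid) >= 0))
  }
  # pairwise pure-spectrum distances clear the default noise floor
  pure <- sapply(ems1, evaluate_endmember, grid = grid)
  D <- as.matrix(dist(t(pure)))
  floor <- 10 * 0.002 * sqrt(grid$n_points)
  expect_gt(min(D[upper.tri(D)]), floor)
})

test_that("evaluate_endmember is a sum of Gaussians", {
  grid <- wn_grid()
  one <- structure(list(class_name = "x",
                        bands = data.frame(center = 5100, width = 50, amplitude = 1),
                        similarity_group = "other"), class = "endmember_spec")
  s <- evaluate_endmember(one, grid)
  k <- which.min(abs(grid$values - 5100))
  off <- grid$values[k] - 5100
  expect_equal(s[k], exp(-off^2 / (2 * 50^2)), tolerance = 1e-12)
  expect_lt(abs(off), abs(grid$values[2] - grid$values[1]))
  # linearity: two half-amplitude copies equal one full band
  two <- one; two$bands <- rbind(one$bands, one$bands); two$bands$amplitude <- 0.5
  expect_equal(evaluate_endmember(two, grid), s, tolerance = 1e-12)
  zero <- one; zero$bands$amplitude <- 0
  expect_equal(evaluate_endmember(zero, grid), numeric(grid$n_points))
  none <- one; none$bands <- one$bands[0, ]
  expect_error(evaluate_endmember(none, grid), "no bands")
})

test_that("generate_spectra honours the default composition and determinism", {
  ds <- default_dataset()
  expect_equal(dim(ds$absorbance), c(275, 1557))
  expect_equal(sum(ds$label == "genuine"), 50)
  expect_equal(sum(ds$label == "adulterated"), 200)
  expect_equal(sum(ds$fraction == 1), 25)
  # 6 pure-class groups, 5 x 4 mixture cells
  expect_equal(length(unique(ds$label[ds$fraction %in% c(0, 1)])), 6)
  cells <- unique(paste(ds$adulterant, ds$fraction)[ds$label == "adulterated"])
  expect_equal(length(cells), 20)
  expect_setequal(unique(ds$fraction), c(0, 0.2, 0.4, 0.6, 0.8, 1))
  # bit-identical regeneration
  again <- generate_spectra(sim_config(seed = 42L))
  expect_identical(ds$absorbance, again$absorbance)
  expect_identical(ds$label, again$label)
  # a different seed changes the data
  other <- generate_spectra(small_config(seed = 8L))
  expect_false(identical(small_dataset()$absorbance, other$absorbance))
})

test_that("mixing is exactly linear with all effects disabled", {
  cfg <- sim_config(seed = 3L, n_genuine_batches = 1L, genuine_reps = 1L,
                    mixture_reps = 1L, adulterant_reps = 1L,
                    fractions = c(0.25, 0.5),
                    noise_sd = 0, scatter_sd = 0,
                    baseline_a0 = c(0, 0), baseline_a1 = c(0, 0),
                    batch_jitter_sd = 0)
  ds <- generate_spectra(cfg)
  ems <- make_endmembers(3L)
  s_dkm <- evaluate_endmember(ems$DKM, cfg$grid)
  for (a in c("DL", "DH", "DKML", "bamboo", "corn")) {
    s_a <- evaluate_endmember(ems[[a]], cfg$grid)
    for (f in c(0.25, 0.5)) {
      i <- which(ds$adulterant == a & ds$fraction == f)
      expect_equal(ds$absorbance[i, ], (1 - f) * s_dkm + f * s_a,
                   tolerance = 1e-15)
    }
  }
})

test_that("invalid configs are rejected", {
  expect_error(sim_config(fractions = c(0.2, 1)), "strictly in")
  expect_error(sim_config(fractions = 0), "strictly in")
})

test_that("separability calibration holds after SNV", {
  ds <- default_dataset()
  Z <- snv(ds$absorbance)
  g <- Z[ds$label == "genuine", ]
  within <- mean(dist(g))
  cen <- colMeans(g)
  centroid_d <- sapply(c("DL", "DH", "DKML", "bamboo", "corn"), function(a)
    sqrt(sum((colMeans(Z[ds$label == a, , drop = FALSE]) - cen)^2)))
  expect_lt(within, min(centroid_d))
})

test_that("CSV round trip preserves the dataset", {
  ds <- small_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, path)
  back <- read_spectra_csv(path)
  expect_identical(back$label, ds$label)
  expect_identical(back$batch, ds$batch)
  expect_equal(back$fraction, ds$fraction, tolerance = 1e-12)
  expect_lt(max(abs(back$absorbance - ds$absorbance)), 1e-10)
  expect_equal(back$grid$values, ds$grid$values, tolerance = 1e-9)
  # one-row set survives
  one <- ds[3]
  write_spectra_csv(one, path)
  expect_equal(n_spectra(read_spectra_csv(path)), 1)
})

test_that("CSV reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  expect_error(read_spectra_csv(path), "empty file")
  writeLines(c("sample_id,label,adulterant,fraction,batch,4000,5000",
               "s1,genuine,NA,0,1,0.1,0.2"), path)
  expect_error(read_spectra_csv(path), "not strictly decreasing")
  expect_error(read_spectra_csv(tempfile()), "not found")
})

test_that("simulation config round-trips through JSON", {
  cfg <- small_config()
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$fractions, cfg$fractions)
  expect_equal(back$noise_sd, cfg$noise_sd)
  expect_identical(generate_spectra(back)$absorbance,
                   generate_spectra(cfg)$absorbance)
})
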