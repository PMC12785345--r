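#' Simulation configuration for the synthetic NIR generator
#'
#' The generator emulates a powdered-herb adulteration study: one genuine
#' class (DKM, *Dendrobium officinale*) sampled in batches, three closely
#' related Dendrobium-type adulterants (DL, DH, DKML), two botanically
#' distant fillers (bamboo, corn), binary DKM-adulterant mixtures at fixed
#' mass fractions, and the instrumental artifacts (multiplicative scatter,
#' linear baseline drift, additive noise) that preprocessing is meant to
#' remove. Defaults yield 275 samples: 10 genuine batches x 5 replicates,
#' 5 adulterants x 4 fractions x 10 replicates, 5 pure adulterants x 5
#' replicates.
#'
#' @param seed root seed; all randomness derives from it via [derive_seed()].
#' @param n_genuine_batches number of genuine DKM batches (default 10).
#' @param genuine_reps replicates per genuine batch (default 5).
#' @param mixture_reps replicates per (adulterant, fraction) cell (default 10).
#' @param adulterant_reps replicates per pure adulterant (default 5).
#' @param fractions adulterant mass fractions for mixtures, each in (0, 1).
#' @param noise_sd additive noise standard deviation, absorbance units.
#' @param scatter_sd log-scale sd of the multiplicative scatter gain.
#' @param baseline_a0,baseline_a1 ranges (length-2) for the intercept and
#'   slope of the per-spectrum linear baseline over the normalized grid.
#' @param batch_jitter_sd relative sd of per-batch band-amplitude jitter.
#' @param grid a [wn_grid()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_genuine_batches = 10L,
                       genuine_reps = 5L,
                       mixture_reps = 10L,
                       adulterant_reps = 5L,
                       fractions = c(0.2, 0.4, 0.6, 0.8),
                       noise_sd = 0.002,
                       scatter_sd = 0.05,
                       baseline_a0 = c(-0.02, 0.02),
                       baseline_a1 = c(-0.05, 0.05),
                       batch_jitter_sd = 0.03,
                       grid = wn_grid()) {
  if (any(fractions <= 0 | fractions >= 1))
    stop_nirauth("mixture fractions must lie strictly in (0, 1)")
  stopifnot(n_genuine_batches >= 1, genuine_reps >= 1, mixture_reps >= 1,
            adulterant_reps >= 1, noise_sd >= 0, scatter_sd >= 0,
            batch_jitter_sd >= 0, length(baseline_a0) == 2,
            length(baseline_a1) == 2)
  structure(list(seed = as.integer(seed),
                 n_genuine_batches = as.integer(n_genuine_batches),
                 genuine_reps = as.integer(genuine_reps),
                 mixture_reps = as.integer(mixture_reps),
                 adulterant_reps = as.integer(adulterant_reps),
                 fractions = as.numeric(fractions),
                 noise_sd = noise_sd, scatter_sd = scatter_sd,
                 baseline_a0 = as.numeric(baseline_a0),
                 baseline_a1 = as.numeric(baseline_a1),
                 batch_jitter_sd = batch_jitter_sd,
                 grid = grid),
            class = "sim_config")
}

#' Read / write a simulation configuration as JSON
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$grid <- list(n_points = config$grid$n_points,
                 high = config$grid$values[1],
                 low = config$grid$values[config$grid$n_points])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$grid <- wn_grid(x$grid$n_points, x$grid$high, x$grid$low)
  do.call(sim_config, x)
}

# canonical DKM band table: the three absorption regions characteristic of
# plant powders (O-H first overtone 7075-6600, sugar O-H/C-H combination
# 5200-5100, C-H overtone / water combination 4800-4600) plus the 5600 and
# high-wavenumber shoulders. Amplitudes in absorbance units; the overall
# scale is calibrated so that instrument noise at the default noise_sd is a
# sub-0.1% share of total dataset variance, matching the compactness regime
# of real powdered-herb NIR (a handful of PCs carry ~99.9% of variance).
dkm_base_bands <- function() {
  data.frame(
    center = c(6830, 6980, 5150, 5600, 4700, 4380, 8350, 9400),
    width  = c(150,   90,   55,   80,   90,   70,  300,  350),
    amplitude = 3.5 * c(0.60, 0.25, 0.90, 0.35, 0.75, 0.30, 0.18, 0.08))
}

# per-class magnitude of the shared band-amplitude contrast. Signs and
# magnitudes are fixed by design: the Dendrobium congeners sit close to DKM
# (DH closest, hence hardest to quantify), the fillers far on either side.
contrast_magnitudes <- c(DH = 0.45, DL = 0.70, DKML = 1.00,
                         bamboo = 1.80, corn = -1.50)

#' Build the six pure-class endmember band tables
#'
#' All classes share the canonical DKM band set. Adulterant classes reweight
#' the band amplitudes along one common composition contrast: the factor for
#' band k in class c is `1 + kappa_c * d_k`, where `d_k` is a fixed
#' alternating-sign contrast pattern (magnitudes drawn once per seed) and
#' `kappa_c` a class magnitude -- small for the Dendrobium congeners (DH
#' closest to DKM), large and of opposite signs for bamboo and corn. Each
#' adulterant additionally carries one or two weak class-unique bands. The
#' rank-one between-class structure emulates the strong collinearity of real
#' powdered-plant NIR spectra, where most spectral variance concentrates in
#' very few principal components.
#'
#' @param seed integer seed; the same seed always yields the same tables.
#' @return named list of 6 `endmember_spec` objects, each with fields
#'   `class_name`, `bands` (data.frame center/width/amplitude) and
#'   `similarity_group` (`"dendrobium"` or `"other"`).
#' @export
make_endmembers <- function(seed = 42L) {
  base <- dkm_base_bands()
  nb <- nrow(base)
  with_stage_seed(seed, "endmembers", {
    d <- rep(c(1, -1), length.out = nb) * runif(nb, 0.12, 0.28)
    kappa <- contrast_magnitudes * (1 + runif(5, -0.08, 0.08))
    specs <- list(DKM = endmember_spec("DKM", base, "dendrobium"))
    for (cls in names(kappa)) {
      bands <- base
      bands$amplitude <- base$amplitude * (1 + kappa[[cls]] * d)
      n_uniq <- if (cls %in% c("bamboo", "corn")) 2L else sample(1:2, 1)
      uniq <- data.frame(center = runif(n_uniq, 4200, 9600),
                         width = runif(n_uniq, 60, 150),
                         amplitude = runif(n_uniq, 0.015, 0.03))
      grp <- if (cls %in% c("bamboo", "corn")) "other" else "dendrobium"
      specs[[cls]] <- endmember_spec(cls, rbind(bands, uniq), grp)
    }
    specs
  })
}

endmember_spec <- function(class_name, bands, similarity_group) {
  stopifnot(all(bands$amplitude >= 0), all(bands$width > 0))
  structure(list(class_name = class_name, bands = bands,
                 similarity_group = similarity_group),
            class = "endmember_spec")
}

#' Evaluate a pure endmember spectrum on a wavenumber grid
#'
#' The spectrum is a sum of Gaussian absorption bands:
#' `s(v) = sum_k a_k * exp(-(v - c_k)^2 / (2 w_k^2))`.
#'
#' @param spec an `endmember_spec`.
#' @param grid a [wn_grid()].
#' @return numeric vector of length `grid$n_points`, nonnegative.
#' @export
evaluate_endmember <- function(spec, grid = wn_grid()) {
  stopifnot(inherits(spec, "endmember_spec"), inherits(grid, "wn_grid"))
  if (nrow(spec$bands) == 0) stop_nirauth("endmember has no bands")
  v <- grid$values
  s <- numeric(grid$n_points)
  for (k in seq_len(nrow(spec$bands))) {
    b <- spec$bands[k, ]
    s <- s + b$amplitude * exp(-(v - b$center)^2 / (2 * b$width^2))
  }
  s
}

#' Generate a synthetic NIR dataset
#'
#' Every sample is a binary mixture `clean = (1 - f) * s_DKM + f * s_adu`
#' of batch-jittered DKM and one adulterant endmember (f = 0 for genuine,
#' f = 1 for pure adulterants), observed through the instrument model
#' `observed = gain * clean + a0 + a1 * v_norm + eps` with log-normal gain,
#' a linear baseline over the grid normalized to \[0, 1\], and iid Gaussian
#' noise. All randomness flows from `config$seed` through stage-wise child
#' seeds, so identical configs give bit-identical datasets.
#'
#' @param config a [sim_config()].
#' @return a [spectra_set()]; with defaults, 275 spectra of 1557 points.
#' @export
generate_spectra <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  ems <- make_endmembers(config$seed)
  adulterants <- c("DL", "DH", "DKML", "bamboo", "corn")
  pure <- vapply(ems, evaluate_endmember, numeric(grid$n_points), grid = grid)

  B <- config$n_genuine_batches
  nb <- nrow(ems$DKM$bands)
  # batch effect: mostly a scalar concentration/packing factor common to all
  # bands (relative sd = batch_jitter_sd), plus per-band micro-variation at a
  # tenth of that, so genuine batches vary mainly along the base spectrum
  jit <- with_stage_seed(config$seed, "batches", {
    eta <- rnorm(B, 1, config$batch_jitter_sd)
    micro <- matrix(rnorm(B * nb, 1, config$batch_jitter_sd / 10), B, nb)
    eta * micro
  })
  jit[jit < 0] <- 0
  dkm_batch <- sapply(seq_len(B), function(b) {
    spec <- ems$DKM
    spec$bands$amplitude <- spec$bands$amplitude * jit[b, ]
    evaluate_endmember(spec, grid)
  })

  rows <- list(); label <- character(); fraction <- numeric()
  batch <- integer(); adu <- character()
  for (b in seq_len(B)) for (r in seq_len(config$genuine_reps)) {
    rows[[length(rows) + 1L]] <- dkm_batch[, b]
    label <- c(label, "genuine"); fraction <- c(fraction, 0)
    batch <- c(batch, b); adu <- c(adu, NA_character_)
  }
  for (a in adulterants) for (f in sort(config$fractions))
    for (r in seq_len(config$mixture_reps)) {
      b <- ((r - 1L) %% B) + 1L
      rows[[length(rows) + 1L]] <- (1 - f) * dkm_batch[, b] + f * pure[, a]
      label <- c(label, "adulterated"); fraction <- c(fraction, f)
      batch <- c(batch, b); adu <- c(adu, a)
    }
  for (a in adulterants) for (r in seq_len(config$adulterant_reps)) {
    rows[[length(rows) + 1L]] <- pure[, a]
    label <- c(label, a); fraction <- c(fraction, 1)
    batch <- c(batch, 0L); adu <- c(adu, a)
  }
  clean <- do.call(rbind, rows)
  n <- nrow(clean)

  v_norm <- (grid$values - min(grid$values)) / diff(range(grid$values))
  obs <- with_stage_seed(config$seed, "noise", {
    gain <- exp(rnorm(n, 0, config$scatter_sd))
    a0 <- runif(n, config$baseline_a0[1], config$baseline_a0[2])
    a1 <- runif(n, config$baseline_a1[1], config$baseline_a1[2])
    eps <- matrix(rnorm(n * grid$n_points, 0, config$noise_sd), n)
    gain * clean + outer(a0, rep(1, grid$n_points)) + outer(a1, v_norm) + eps
  })
  spectra_set(grid, obs, label, fraction, batch, adu)
}
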