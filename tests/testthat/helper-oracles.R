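# independent oracles and shared fixtures for the test suite

# brute-force Kennard-Stone: literal maximin with lowest-index tie-breaks,
# O(n^2 k); usable up to ~12 points
ks_bruteforce <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(NA, NA); bestd <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(1:n, sel)
    md <- sapply(cand, function(i) min(D[i, sel]))
    sel <- c(sel, cand[which(md == max(md))[1]])
  }
  sel
}

# closed-form simple linear regression (normal equations) for the MSC oracle
ols2 <- function(x, ref) {
  b <- sum((ref - mean(ref)) * (x - mean(x))) / sum((ref - mean(ref))^2)
  a <- mean(x) - b * mean(ref)
  c(a = a, b = b)
}

# tiny default-structure dataset shared by slower tests (computed once)
.fixtures <- new.env()
small_config <- function(seed = 7L) {
  sim_config(seed = seed, n_genuine_batches = 5L, genuine_reps = 3L,
             mixture_reps = 3L, adulterant_reps = 2L)
}
small_dataset <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- generate_spectra(small_config())
  .fixtures$small
}

# the default seed-42 study dataset used by the acceptance criteria
default_dataset <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- generate_spectra(sim_config(seed = 42L))
  .fixtures$default
}

# SG-pretreated spectra + stratified 6:2:2 split of the default dataset
default_study <- function() {
  if (is.null(.fixtures$study)) {
    ds <- default_dataset()
    delta <- -diff(range(ds$grid$values)) / (ds$grid$n_points - 1)
    pp <- fit_pipeline(preprocess_pipeline("SG"), ds$absorbance, delta)
    Z <- transform_pipeline(pp, ds$absorbance)
    binary <- ifelse(ds$label == "genuine", "genuine", "adulterated")
    .fixtures$study <- list(ds = ds, Z = Z, binary = binary,
                            split = split_622(Z, binary))
  }
  .fixtures$study
}
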