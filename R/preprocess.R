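#' Standard normal variate transform
#'
#' Centers and scales every spectrum (row) to mean 0 and unit sample standard
#' deviation (denominator n - 1). Removes per-spectrum multiplicative scatter
#' and additive offsets.
#'
#' @param X numeric matrix, spectra in rows.
#' @return transformed matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1))
  if (any(s == 0))
    stop_nirauth("SNV: constant spectrum in row ", which(s == 0)[1])
  (X - m) / s
}

#' Multiplicative scatter correction
#'
#' `msc_fit` learns the reference spectrum (column mean of the calibration
#' matrix); `msc_apply` regresses each spectrum on the reference,
#' `x ~ a + b * ref`, and returns `(x - a) / b`. The reference is fitted on
#' calibration data only and reused unchanged for any later matrix
#' (train/test hygiene).
#'
#' @param calibration numeric matrix of calibration spectra (rows).
#' @param X matrix of spectra to correct.
#' @param reference reference spectrum from `msc_fit`.
#' @return `msc_fit`: numeric reference vector. `msc_apply`: corrected matrix.
#' @export
msc_fit <- function(calibration) {
  calibration <- as.matrix(calibration)
  if (nrow(calibration) == 0) stop_nirauth("MSC: empty calibration matrix")
  colMeans(calibration)
}

#' @rdname msc_fit
#' @export
msc_apply <- function(X, reference) {
  X <- as.matrix(X)
  if (ncol(X) != length(reference))
    stop_nirauth("MSC: reference length ", length(reference),
                 " does not match spectrum length ", ncol(X))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  b <- as.vector(X %*% rc) / denom         # closed-form simple OLS slope
  a <- rowMeans(X) - b * mean(reference)
  if (any(abs(b) < 1e-12))
    stop_nirauth("MSC: degenerate scatter fit (|b| < 1e-12) in row ",
                 which(abs(b) < 1e-12)[1])
  (X - a) / b
}

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares polynomial filter coefficients from the local design matrix:
#' fitting a degree-`polyorder` polynomial over a centred window of
#' `window` points and reading off the value (or `deriv`-th derivative) at
#' the window centre.
#'
#' @param window odd window length.
#' @param polyorder polynomial order, `< window`.
#' @param deriv derivative order (0, 1 or 2).
#' @return numeric coefficient vector of length `window`.
#' @export
savgol_coef <- function(window, polyorder, deriv = 0) {
  if (window %% 2 == 0) stop_nirauth("SG window must be odd")
  if (window <= polyorder) stop_nirauth("SG window must exceed polynomial order")
  if (deriv > polyorder) stop_nirauth("SG derivative order exceeds polynomial order")
  m <- (window - 1) / 2
  A <- outer(-m:m, 0:polyorder, `^`)
  # row `deriv` of the pseudoinverse times deriv! gives the derivative filter
  pinv <- solve(crossprod(A), t(A))
  factorial(deriv) * pinv[deriv + 1, ]
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Applies the SG filter along each spectrum. Interior points use the
#' convolution coefficients; each edge is handled by fitting the boundary
#' window's polynomial and evaluating it (and its derivatives) at the edge
#' positions, so polynomials up to the fitted order are reproduced exactly
#' everywhere. Derivatives are divided by `delta^deriv` (the signed grid
#' spacing) so units are AU per cm^-1 or AU per cm^-2.
#'
#' @param X matrix of spectra (rows).
#' @param window odd window length (default 15).
#' @param polyorder polynomial order (default 2).
#' @param deriv derivative order 0, 1 or 2.
#' @param delta grid spacing in cm^-1 (signed; default 1 = index units).
#' @return filtered matrix, same shape as `X`.
#' @export
savgol <- function(X, window = 15L, polyorder = 2L, deriv = 0L, delta = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (window > p) stop_nirauth("SG window (", window, ") exceeds spectrum length (", p, ")")
  op <- savgol_operator(p, window, polyorder, deriv)
  as.matrix(X %*% Matrix::t(op)) / delta^deriv
}

# sparse p x p linear operator for the SG filter incl. polynomial edge rows
savgol_operator <- function(p, window, polyorder, deriv) {
  m <- (window - 1) / 2
  centre <- savgol_coef(window, polyorder, deriv)
  ii <- rep((m + 1):(p - m), each = window)
  jj <- as.vector(vapply((m + 1):(p - m), function(i) (i - m):(i + m),
                         integer(window)))
  xx <- rep(centre, p - 2 * m)
  # edge rows: fit the first/last window, evaluate at each edge offset
  A <- outer(-m:m, 0:polyorder, `^`)
  pinv <- solve(crossprod(A), t(A))      # (polyorder+1) x window
  dcoef <- factorial(deriv)
  for (e in seq_len(m)) {
    off <- e - m - 1                      # position within the first window
    pow <- sapply(0:polyorder, function(k)
      if (k < deriv) 0 else prod(seq(k, by = -1, length.out = deriv)) *
        off^(k - deriv))
    row <- as.vector(pow %*% pinv)
    ii <- c(ii, rep(e, window)); jj <- c(jj, 1:window); xx <- c(xx, row)
    off2 <- m + 1 - e                     # mirrored position, last window
    pow2 <- sapply(0:polyorder, function(k)
      if (k < deriv) 0 else prod(seq(k, by = -1, length.out = deriv)) *
        off2^(k - deriv))
    row2 <- as.vector(pow2 %*% pinv)
    ii <- c(ii, rep(p + 1 - e, window)); jj <- c(jj, (p - window + 1):p)
    xx <- c(xx, row2)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(p, p))
}

#' Finite-difference spectral derivatives
#'
#' The bare "1st Der"/"2nd Der" treatments: central differences in the
#' interior, one-sided differences at the edges, scaled by the (signed) grid
#' spacing. Length is preserved.
#'
#' @param X matrix of spectra (rows).
#' @param order derivative order, 1 or 2.
#' @param delta grid spacing in cm^-1 (signed; default 1).
#' @return matrix of derivatives, same shape as `X`.
#' @export
spectral_derivative <- function(X, order = 1L, delta = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < order + 1) stop_nirauth("need at least ", order + 1, " points")
  if (!order %in% 1:2) stop_nirauth("order must be 1 or 2")
  if (order == 1) {
    D <- cbind(X[, 2] - X[, 1],
               (X[, 3:p, drop = FALSE] - X[, 1:(p - 2), drop = FALSE]) / 2,
               X[, p] - X[, p - 1]) / delta
  } else {
    if (p < 3) stop_nirauth("need at least 3 points for a second derivative")
    inner <- (X[, 3:p, drop = FALSE] - 2 * X[, 2:(p - 1), drop = FALSE] +
                X[, 1:(p - 2), drop = FALSE]) / delta^2
    D <- cbind(inner[, 1], inner, inner[, p - 2])
  }
  unname(D)
}

## ---- pipeline registry -----------------------------------------------------

pipeline_def <- function(name, scatter = NULL, deriv = 0L, sg = FALSE,
                         sg_window = 15L, sg_polyorder = 2L) {
  structure(list(name = name, scatter = scatter, deriv = as.integer(deriv),
                 sg = sg, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 fitted_state = NULL),
            class = "preproc_pipeline")
}

#' The registry of named preprocessing pipelines
#'
#' Exactly the 15 screened treatments: RAW; first/second derivatives with and
#' without SG; MSC and SNV alone and combined with each derivative with and
#' without SG. Scatter correction always precedes differentiation; "+ SG"
#' means the derivative is computed with a fused Savitzky-Golay
#' smoothing-differentiation filter, while the bare derivatives are finite
#' differences. `preprocess_pipeline` additionally accepts `"SG"` (smoothing
#' only), the default pretreatment for one-class modelling, which is not part
#' of the screening registry.
#'
#' @param sg_window,sg_polyorder SG filter parameters used by every "+ SG"
#'   pipeline (defaults 15 and 2).
#' @return `pipeline_registry`: named list of 15 `preproc_pipeline` objects.
#' @export
pipeline_registry <- function(sg_window = 15L, sg_polyorder = 2L) {
  mk <- function(name, scatter, deriv, sg)
    pipeline_def(name, scatter, deriv, sg, sg_window, sg_polyorder)
  out <- list(
    mk("RAW", NULL, 0, FALSE),
    mk("1st Der + SG", NULL, 1, TRUE),
    mk("1st Der", NULL, 1, FALSE),
    mk("2nd Der + SG", NULL, 2, TRUE),
    mk("2nd Der", NULL, 2, FALSE),
    mk("MSC + 1st Der + SG", "MSC", 1, TRUE),
    mk("MSC + 1st Der", "MSC", 1, FALSE),
    mk("MSC + 2nd Der + SG", "MSC", 2, TRUE),
    mk("MSC + 2nd Der", "MSC", 2, FALSE),
    mk("MSC", "MSC", 0, FALSE),
    mk("SNV + 1st Der + SG", "SNV", 1, TRUE),
    mk("SNV + 1st Der", "SNV", 1, FALSE),
    mk("SNV + 2nd Der + SG", "SNV", 2, TRUE),
    mk("SNV + 2nd Der", "SNV", 2, FALSE),
    mk("SNV", "SNV", 0, FALSE))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' @rdname pipeline_registry
#' @param name pipeline name, e.g. `"SNV + 1st Der + SG"`.
#' @export
preprocess_pipeline <- function(name, sg_window = 15L, sg_polyorder = 2L) {
  if (name == "SG")
    return(pipeline_def("SG", NULL, 0L, TRUE, sg_window, sg_polyorder))
  reg <- pipeline_registry(sg_window, sg_polyorder)
  if (!name %in% names(reg))
    stop_nirauth("unknown pipeline '", name, "'; registry holds: ",
                 paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Fit and apply a preprocessing pipeline with train/test hygiene
#'
#' `fit_pipeline` learns any data-dependent state (the MSC reference) from
#' the calibration matrix only. `transform_pipeline` applies a fitted
#' pipeline to any matrix without re-estimating state. `apply_pipeline` is
#' the one-shot convenience wrapper: fit on `calibration`, transform
#' `calibration` and every matrix in `others` with the same fitted state.
#'
#' @param pipeline a `preproc_pipeline` (see [preprocess_pipeline()]).
#' @param calibration calibration matrix (spectra in rows).
#' @param others list of further matrices to transform with the fitted state.
#' @param X matrix to transform.
#' @param delta signed grid spacing (cm^-1 per point) used to scale
#'   derivatives; default 1.
#' @return `apply_pipeline`: list with `calibration` and `others`.
#' @export
fit_pipeline <- function(pipeline, calibration, delta = 1) {
  stopifnot(inherits(pipeline, "preproc_pipeline"))
  if (nrow(as.matrix(calibration)) == 0)
    stop_nirauth("empty calibration matrix")
  pipeline$delta <- delta
  if (identical(pipeline$scatter, "MSC"))
    pipeline$fitted_state <- list(reference = msc_fit(calibration))
  pipeline$fitted <- TRUE
  pipeline
}

#' @rdname fit_pipeline
#' @export
transform_pipeline <- function(pipeline, X) {
  stopifnot(inherits(pipeline, "preproc_pipeline"))
  if (!isTRUE(pipeline$fitted))
    stop_nirauth("pipeline '", pipeline$name, "' is not fitted; call fit_pipeline()")
  if (identical(pipeline$scatter, "MSC") && is.null(pipeline$fitted_state))
    stop_nirauth("MSC pipeline has no fitted reference spectrum")
  X <- as.matrix(X)
  delta <- pipeline$delta %||% 1
  if (identical(pipeline$scatter, "SNV")) X <- snv(X)
  if (identical(pipeline$scatter, "MSC"))
    X <- msc_apply(X, pipeline$fitted_state$reference)
  if (pipeline$deriv > 0) {
    X <- if (pipeline$sg)
      savgol(X, pipeline$sg_window, pipeline$sg_polyorder, pipeline$deriv, delta)
    else spectral_derivative(X, pipeline$deriv, delta)
  } else if (pipeline$sg) {
    X <- savgol(X, pipeline$sg_window, pipeline$sg_polyorder, 0L, delta)
  }
  X
}

#' @rdname fit_pipeline
#' @export
apply_pipeline <- function(pipeline, calibration, others = list(), delta = 1) {
  fitted <- fit_pipeline(pipeline, calibration, delta)
  list(calibration = transform_pipeline(fitted, calibration),
       others = lapply(others, transform_pipeline, pipeline = fitted),
       pipeline = fitted)
}
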