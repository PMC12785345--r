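#' PLS1 regression (NIPALS)
#'
#' Mean-centred NIPALS partial least squares with a single response, here
#' the adulterant mass fraction in \[0, 1\]. The regression vector is
#' `b = W (P'W)^-1 q`, and predictions are
#' `yhat = y_mean + (x - x_mean) b`.
#'
#' @param X numeric matrix, samples in rows.
#' @param y numeric response vector.
#' @param n_lv number of latent variables, `<= min(n - 1, p)`.
#' @return a `plsr_model`.
#' @export
pls1_fit <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_nirauth("X and y dimensions disagree")
  if (stats::var(y) == 0) stop_nirauth("constant response: nothing to regress")
  if (n_lv > min(n - 1, p))
    stop_nirauth("n_lv = ", n_lv, " exceeds min(n - 1, p) = ", min(n - 1, p))
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xd <- sweep(X, 2, x_mean); yd <- y - y_mean
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 || sum(Xd^2) < 1e-24) break   # response fully explained
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    pv <- crossprod(Xd, tt) / tt2
    qa <- sum(yd * tt) / tt2
    Xd <- Xd - tt %*% t(pv)
    yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
    used <- a
  }
  if (used == 0L) stop_nirauth("PLS1: no extractable component")
  W <- W[, 1:used, drop = FALSE]; P <- P[, 1:used, drop = FALSE]; q <- q[1:used]
  R <- W %*% solve(crossprod(P, W))      # so that T = Xc %*% R
  b <- R %*% q
  structure(list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
                 R = R, b = as.vector(b), n_lv = used),
            class = "plsr_model")
}

#' @export
predict.plsr_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean))
    stop_nirauth("variable count mismatch")
  if (n_lv > object$n_lv) stop_nirauth("model has only ", object$n_lv, " components")
  b <- object$R[, 1:n_lv, drop = FALSE] %*% object$q[1:n_lv]
  as.vector(object$y_mean + sweep(X, 2, object$x_mean) %*% b)
}

#' Latent-variable selection by cross-validated RMSECV
#'
#' 10-fold (by default) cross-validation: folds are a seeded shuffle cut
#' into contiguous blocks. One PLS1 model per fold is fitted at the maximum
#' order and truncated, so the RMSECV curve over `1..max_lv` comes from a
#' single pass. The chosen order is the argmin; ties go to the smaller
#' order.
#'
#' @param X matrix of calibration spectra.
#' @param y response vector.
#' @param max_lv largest latent-variable count to consider (default 12).
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return list with `n_lv` (best order) and `rmsecv` (curve over 1..max_lv).
#' @export
select_lv <- function(X, y, max_lv = 12L, folds = 10L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds > n) stop_nirauth("more folds (", folds, ") than samples (", n, ")")
  max_lv <- min(max_lv, n - ceiling(n / folds) - 1, ncol(X))
  fold_idx <- cv_folds(n, folds, seed)
  sse <- numeric(max_lv)
  for (f in fold_idx) {
    fit <- pls1_fit(X[-f, , drop = FALSE], y[-f], max_lv)
    for (a in seq_len(max_lv)) {
      pred <- predict(fit, X[f, , drop = FALSE], n_lv = min(a, fit$n_lv))
      sse[a] <- sse[a] + sum((y[f] - pred)^2)
    }
  }
  rmsecv <- sqrt(sse / n)
  list(n_lv = which.min(rmsecv), rmsecv = rmsecv)
}

#' Regression evaluation metrics
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`, `MAE = mean(|y - yhat|)`,
#' `R2 = 1 - SS_res / SS_tot` (SS_tot about the evaluated set's own mean),
#' `RPD = sd(y) / RMSE` with sample sd. A perfect fit yields `RPD = Inf`.
#'
#' @param y_true reference values (non-constant, length >= 2).
#' @param y_pred predictions.
#' @return list with `RMSE`, `R2`, `MAE`, `RPD`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_nirauth("length mismatch")
  if (length(y_true) < 2) stop_nirauth("need at least 2 observations")
  if (stats::var(y_true) == 0)
    stop_nirauth("constant reference values: R2 and RPD are undefined")
  err <- y_true - y_pred
  rmse <- sqrt(mean(err^2))
  list(RMSE = rmse,
       R2 = 1 - sum(err^2) / sum((y_true - mean(y_true))^2),
       MAE = mean(abs(err)),
       RPD = if (rmse == 0) Inf else stats::sd(y_true) / rmse,
       n = length(y_true))
}

#' Preprocessing screening harness for one DKM-adulterant series
#'
#' Extracts the binary mixture series for one adulterant (genuine spectra at
#' fraction 0, mixtures, and the pure adulterant at fraction 1), splits it
#' 7:3 by Kennard-Stone on the raw spectra, and for each of the 15 registry
#' pipelines: fits the preprocessing on the calibration set, selects the
#' latent-variable count by 10-fold RMSECV, refits, and reports calibration
#' and prediction metrics. The best pipeline is flagged by prediction R2
#' with RMSEP as tie-break.
#'
#' @param dataset a [spectra_set()] containing the series.
#' @param pair adulterant class name (e.g. `"corn"`).
#' @param seed seed for the cross-validation folds.
#' @param max_lv largest latent-variable count screened (default 12).
#' @param folds cross-validation folds (default 10).
#' @param sg_window,sg_polyorder SG parameters for the "+ SG" pipelines.
#' @return a `data.frame` (class `screening_grid`) with one row per
#'   pipeline: `pipeline`, `n_lv`, prediction `RMSEP/R2p/MAEp/RPDp`,
#'   calibration `RMSEC/R2c/MAEc/RPDc`, and logical `best`.
#' @export
plsr_screen <- function(dataset, pair, seed = 42L, max_lv = 12L, folds = 10L,
                        sg_window = 15L, sg_polyorder = 2L) {
  stopifnot(inherits(dataset, "spectra_set"))
  with_pair <- !is.na(dataset$adulterant) & dataset$adulterant == pair
  if (!any(with_pair)) stop_nirauth("no samples for adulterant '", pair, "'")
  keep <- dataset$label == "genuine" | with_pair
  sub <- dataset[keep]
  lv <- sort(unique(sub$fraction))
  if (!all(c(0, 1) %in% lv) || length(lv) < 4)
    stop_nirauth("series for '", pair, "' is missing fraction levels (need 0, ",
                 "intermediate mixtures, and 1; found: ",
                 paste(lv, collapse = ", "), ")")
  delta <- wn_spacing(sub$grid)
  sp <- split_73(sub$absorbance)
  Xc <- sub$absorbance[sp$train_idx, , drop = FALSE]
  Xp <- sub$absorbance[sp$test_idx, , drop = FALSE]
  yc <- sub$fraction[sp$train_idx]; yp <- sub$fraction[sp$test_idx]
  reg <- pipeline_registry(sg_window, sg_polyorder)
  rows <- lapply(reg, function(pl) {
    tr <- apply_pipeline(pl, Xc, list(Xp), delta)
    Zc <- tr$calibration; Zp <- tr$others[[1]]
    sel <- select_lv(Zc, yc, max_lv = max_lv, folds = folds, seed = seed)
    fit <- pls1_fit(Zc, yc, sel$n_lv)
    mc <- regression_metrics(yc, predict(fit, Zc))
    mp <- regression_metrics(yp, predict(fit, Zp))
    data.frame(pipeline = pl$name, n_lv = fit$n_lv,
               RMSEP = mp$RMSE, R2p = mp$R2, MAEp = mp$MAE, RPDp = mp$RPD,
               RMSEC = mc$RMSE, R2c = mc$R2, MAEc = mc$MAE, RPDc = mc$RPD,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ord <- order(-grid$R2p, grid$RMSEP)
  grid$best <- seq_len(nrow(grid)) == ord[1]
  class(grid) <- c("screening_grid", "data.frame")
  attr(grid, "pair") <- pair
  grid
}
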