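#' Principal component analysis of a spectral matrix
#'
#' Mean-centred SVD. Eigenvalues are the score variances (denominator n - 1);
#' explained-variance fractions are eigenvalues over total column variance.
#'
#' @param X numeric matrix, samples in rows.
#' @param A number of components to retain (default `min(n - 1, p)`).
#' @param center logical; mean-centre columns first (default TRUE).
#' @return a `pca_model` with fields `mean`, `loadings` (p x A, orthonormal),
#'   `scores` (n x A), `eigenvalues`, `explained`, `cumulative`.
#' @export
pca_fit <- function(X, A = NULL, center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  maxA <- min(n - 1, p)
  if (is.null(A)) A <- maxA
  if (A > maxA) stop_nirauth("A = ", A, " exceeds min(n - 1, p) = ", maxA)
  mu <- if (center) colMeans(X) else numeric(p)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = A, nv = A)
  eig <- sv$d^2 / (n - 1)
  total <- sum(Xc^2) / (n - 1)
  structure(list(mean = mu, loadings = sv$v,
                 scores = sv$u %*% diag(sv$d[seq_len(A)], A, A),
                 eigenvalues = eig[seq_len(A)],
                 explained = eig[seq_len(A)] / total,
                 cumulative = cumsum(eig[seq_len(A)] / total),
                 total_variance = total, A = A, center = center),
            class = "pca_model")
}

#' Project new spectra onto a fitted PCA model
#' @param model a `pca_model`.
#' @param X matrix on the same variable grid.
#' @return n x A score matrix.
#' @export
pca_project <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop_nirauth("variable count mismatch: model has ", length(model$mean),
                 ", data has ", ncol(X))
  sweep(X, 2, model$mean) %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d components, cumulative explained variance %.4f\n",
              x$A, x$cumulative[x$A]))
  invisible(x)
}

one_hot <- function(labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  Y <- outer(labels, classes, `==`) * 1
  colnames(Y) <- classes
  Y
}

# NIPALS PLS2: X (n x p) and Y (n x q), both already centred
nipals_pls2 <- function(Xc, Yc, A, tol = 1e-10, max_iter = 500) {
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, q, A)
  Tm <- matrix(0, n, A)
  Xd <- Xc; Yd <- Yc
  used <- 0L
  for (a in seq_len(A)) {
    if (sum(Yd^2) < 1e-24 || sum(Xd^2) < 1e-24) break  # Y or X exhausted
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      qv <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% qv / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pv <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(pv)
    Yd <- Yd - tt %*% t(qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
    used <- a
  }
  if (used == 0L) stop_nirauth("PLS: no extractable component (X or Y constant)")
  W <- W[, 1:used, drop = FALSE]; P <- P[, 1:used, drop = FALSE]
  Q <- Q[, 1:used, drop = FALSE]; Tm <- Tm[, 1:used, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(W = W, P = P, Q = Q, T = Tm, B = B, A = used)
}

pls2_fit_stats <- function(Xc, Yc, fit) {
  ssx <- sum(Xc^2); ssy <- sum(Yc^2)
  Yhat <- Xc %*% fit$B
  Xhat <- fit$T %*% t(fit$P)
  list(R2X = 1 - sum((Xc - Xhat)^2) / ssx,
       R2Y = 1 - sum((Yc - Yhat)^2) / ssy)
}

# seeded shuffle-then-contiguous fold assignment
cv_folds <- function(n, folds, seed) {
  if (folds > n) stop_nirauth("more folds (", folds, ") than samples (", n, ")")
  perm <- with_stage_seed(seed, "cv_folds", sample.int(n))
  split(perm, cut(seq_len(n), folds, labels = FALSE))
}

#' Partial least squares discriminant analysis
#'
#' NIPALS PLS2 on mean-centred spectra against one-hot class indicators.
#' Classes are predicted by the argmax of the predicted indicators. Q2 is
#' computed from K-fold cross-validated PRESS: `Q2 = 1 - PRESS / SS(Y)`,
#' with seeded, reproducible folds.
#'
#' @param X numeric matrix, samples in rows.
#' @param labels per-sample class labels (at least 2 classes).
#' @param A number of latent components.
#' @param cv_folds number of cross-validation folds (default 7).
#' @param seed seed for the fold assignment.
#' @return a `discriminant_model` with `R2X`, `R2Y`, `Q2`, loadings/weights
#'   and a `predict` method.
#' @export
plsda_fit <- function(X, labels, A, cv_folds = 7L, seed = 1L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_nirauth("PLS-DA needs at least 2 classes")
  Y <- one_hot(labels)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  fit <- nipals_pls2(Xc, Yc, A)
  stats <- pls2_fit_stats(Xc, Yc, fit)
  # cross-validated PRESS
  folds <- cv_folds(nrow(X), cv_folds, seed)
  press <- 0
  for (f in folds) {
    xm <- colMeans(X[-f, , drop = FALSE]); ym <- colMeans(Y[-f, , drop = FALSE])
    ft <- nipals_pls2(sweep(X[-f, , drop = FALSE], 2, xm),
                      sweep(Y[-f, , drop = FALSE], 2, ym), A)
    pred <- sweep(sweep(X[f, , drop = FALSE], 2, xm) %*% ft$B, 2, ym, `+`)
    press <- press + sum((Y[f, , drop = FALSE] - pred)^2)
  }
  Q2 <- 1 - press / sum(Yc^2)
  structure(list(kind = "PLSDA", classes = classes, A = A,
                 x_mean = x_mean, y_mean = y_mean,
                 W = fit$W, P = fit$P, Q = fit$Q, B = fit$B,
                 R2X = stats$R2X, R2Y = stats$R2Y, Q2 = Q2),
            class = "discriminant_model")
}

#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (object$kind == "OPLSDA" && object$n_orth > 0)
    X <- oplsda_filter(object, X)
  Yhat <- sweep(sweep(X, 2, object$x_mean) %*% object$B, 2, object$y_mean, `+`)
  object$classes[max.col(Yhat, ties.method = "first")]
}

# remove the fitted orthogonal components from new (uncentred) data
oplsda_filter <- function(model, X) {
  Xc <- sweep(X, 2, model$x_mean)
  for (j in seq_len(model$n_orth)) {
    t_o <- Xc %*% model$W_orth[, j]
    Xc <- Xc - t_o %*% t(model$P_orth[, j])
  }
  sweep(Xc, 2, model$x_mean, `+`)
}

#' Orthogonal PLS discriminant analysis
#'
#' Removes `n_orth` components of X-variation orthogonal to the class
#' indicators (orthogonal signal correction in the projection sense), then
#' fits a PLS-DA model on the filtered spectra. With `n_orth = 0` this
#' coincides with PLS-DA.
#'
#' @inheritParams plsda_fit
#' @param n_orth number of orthogonal components to remove.
#' @param A predictive components for the final PLS-DA fit (default 1 for
#'   two classes, `n_classes` otherwise).
#' @return a `discriminant_model` of kind `"OPLSDA"` with the additional
#'   fields `W_orth`, `P_orth`, `T_orth` and `n_orth`.
#' @export
oplsda_fit <- function(X, labels, n_orth, A = NULL, cv_folds = 7L, seed = 1L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_nirauth("OPLS-DA needs at least 2 classes")
  if (n_orth >= qr(sweep(X, 2, colMeans(X)))$rank)
    stop_nirauth("n_orth must be smaller than rank of centred X")
  if (is.null(A)) A <- if (length(classes) == 2) 1L else length(classes)
  Y <- one_hot(labels)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, colMeans(Y))
  p <- ncol(X)
  W_orth <- matrix(0, p, max(n_orth, 1))
  P_orth <- matrix(0, p, max(n_orth, 1))
  T_orth <- matrix(0, nrow(X), max(n_orth, 1))
  Xd <- Xc
  if (n_orth > 0) for (j in seq_len(n_orth)) {
    f1 <- nipals_pls2(Xd, Yc, 1)
    w <- f1$W[, 1]; pv <- f1$P[, 1]
    w_o <- pv - sum(w * pv) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break
    w_o <- w_o / nrm
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - t_o %*% t(p_o)
    W_orth[, j] <- w_o; P_orth[, j] <- p_o; T_orth[, j] <- t_o
  }
  X_filt <- sweep(Xd, 2, x_mean, `+`)
  base <- plsda_fit(X_filt, labels, A, cv_folds, seed)
  base$kind <- "OPLSDA"
  base$n_orth <- as.integer(n_orth)
  base$W_orth <- W_orth; base$P_orth <- P_orth; base$T_orth <- T_orth
  base$x_mean <- x_mean   # filtering and prediction share one centring
  base
}
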