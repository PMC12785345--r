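#' Score and orthogonal distances under a PCA model
#'
#' For each spectrum, the score distance `h = sum_a t_a^2 / lambda_a`
#' (leverage within the principal-component subspace) and the orthogonal
#' distance `v = ||x - xhat||^2` (squared residual norm outside it).
#'
#' @param pca a `pca_model` from [pca_fit()].
#' @param X numeric matrix on the same variable grid.
#' @param n_pc number of components to use (default: all retained).
#' @return list with numeric vectors `h` and `v`, both nonnegative.
#' @export
dds_distances <- function(pca, X, n_pc = pca$A) {
  stopifnot(inherits(pca, "pca_model"))
  if (n_pc > pca$A) stop_nirauth("n_pc exceeds the components retained in the PCA")
  lam <- pca$eigenvalues[seq_len(n_pc)]
  if (any(lam <= 0))
    stop_nirauth("zero eigenvalue among the retained components")
  Tn <- pca_project(pca, X)[, seq_len(n_pc), drop = FALSE]
  h <- as.vector(Tn^2 %*% (1 / lam))
  Xc <- sweep(as.matrix(X), 2, pca$mean)
  resid <- Xc - Tn %*% t(pca$loadings[, seq_len(n_pc), drop = FALSE])
  v <- rowSums(resid^2)
  list(h = unname(h), v = unname(pmax(v, 0)))
}

#' Method-of-moments degrees of freedom for a scaled chi-squared
#'
#' Fits `d ~ (d0 / N) * chi2(N)` by moment matching: the scaling factor is
#' the sample mean and `N = round(2 * mean(d)^2 / var(d))`, clipped to
#' `[1, 250]`. A degenerate (zero-variance but positive-mean) sample hits the
#' upper clip.
#'
#' @param d nonnegative distance vector.
#' @return list with `d0` (mean) and integer `N`.
#' @export
estimate_dof <- function(d) {
  if (length(d) == 0) stop_nirauth("empty distance vector")
  if (any(d < 0)) stop_nirauth("distances must be nonnegative")
  d0 <- mean(d)
  if (d0 == 0) stop_nirauth("all distances are zero: degenerate class model")
  v <- stats::var(d)
  N <- if (v == 0) 250L else as.integer(min(250, max(1, round(2 * d0^2 / v))))
  list(d0 = d0, N = N)
}

#' Fit a data-driven SIMCA one-class model
#'
#' PCA is fitted on genuine calibration spectra only. Score and orthogonal
#' distances of the calibration samples yield scaling factors (h0, v0) and
#' chi-squared degrees of freedom (N_h, N_v) by moment matching; the total
#' distance `c = N_h * h / h0 + N_v * v / v0` is referred to a chi-squared
#' law with `N_h + N_v` degrees of freedom. The acceptance threshold is its
#' `1 - alpha` quantile; the outlier threshold uses the per-sample level
#' `(1 - gamma)^(1/n)` so the chance of flagging any calibration sample as
#' an outlier is about `gamma`.
#'
#' @param X genuine calibration spectra (matrix, rows = samples).
#' @param n_pc number of principal components.
#' @param alpha Type I error rate for the acceptance region (default 0.01).
#' @param gamma outlier significance level (default 0.01).
#' @param labels optional labels for `X`; anything other than `"genuine"`
#'   aborts (one-class contract).
#' @return a `dd_simca` model.
#' @export
dds_fit <- function(X, n_pc = 7L, alpha = 0.01, gamma = 0.01, labels = NULL) {
  X <- as.matrix(X)
  if (!is.null(labels) && any(labels != "genuine"))
    stop_nirauth("one-class contract violated: training data contain non-genuine labels")
  if (n_pc >= nrow(X)) stop_nirauth("n_pc must be smaller than the number of training samples")
  pca <- pca_fit(X, A = n_pc)
  d <- dds_distances(pca, X, n_pc)
  eh <- estimate_dof(d$h)
  ev <- estimate_dof(d$v)
  dof <- eh$N + ev$N
  c_crit <- stats::qchisq(1 - alpha, dof)
  c_out <- stats::qchisq((1 - gamma)^(1 / nrow(X)), dof)
  structure(list(pca = pca, n_pc = as.integer(n_pc),
                 h0 = eh$d0, v0 = ev$d0, N_h = eh$N, N_v = ev$N,
                 alpha = alpha, gamma = gamma,
                 c_crit = c_crit, c_out = max(c_out, c_crit),
                 n_train = nrow(X)),
            class = "dd_simca")
}

#' @export
print.dd_simca <- function(x, ...) {
  cat(sprintf(paste0("DD-SIMCA model: %d PCs, N_h=%d, N_v=%d, alpha=%g, ",
                     "c_crit=%.3f, c_out=%.3f\n"),
              x$n_pc, x$N_h, x$N_v, x$alpha, x$c_crit, x$c_out))
  invisible(x)
}

#' Classify spectra with a fitted DD-SIMCA model
#'
#' @param object a `dd_simca` model.
#' @param newdata matrix of spectra on the model's variable grid.
#' @param ... unused.
#' @return data.frame with per-sample `h`, `v`, total distance `c`, the
#'   acceptance-plot coordinates `log1p_h = log(1 + h/h0)` and
#'   `log1p_v = log(1 + v/v0)`, and `verdict` in
#'   `{"genuine", "adulterated", "outlier"}` (outlier = beyond the outlier
#'   threshold; both non-genuine verdicts are rejections).
#' @export
predict.dd_simca <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$pca$mean))
    stop_nirauth("grid mismatch: model has ", length(object$pca$mean),
                 " variables, data has ", ncol(X))
  d <- dds_distances(object$pca, X, object$n_pc)
  cc <- object$N_h * d$h / object$h0 + object$N_v * d$v / object$v0
  verdict <- ifelse(cc <= object$c_crit, "genuine",
                    ifelse(cc <= object$c_out, "adulterated", "outlier"))
  data.frame(h = d$h, v = d$v, c = cc,
             log1p_h = log1p(d$h / object$h0), log1p_v = log1p(d$v / object$v0),
             verdict = verdict, stringsAsFactors = FALSE)
}

#' One-class confusion report
#'
#' Genuine is the positive class: sensitivity = TP/(TP+FN) over truly
#' genuine samples, specificity = TN/(TN+FP) over truly adulterated ones.
#'
#' @param decisions data.frame from [predict.dd_simca()] (or any object with
#'   a `verdict` column), or a character vector of verdicts.
#' @param labels true labels; `"genuine"` is positive, anything else negative.
#' @return a `one_class_report` list with `TP`, `FN`, `TN`, `FP`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
dds_evaluate <- function(decisions, labels) {
  verdict <- if (is.character(decisions)) decisions else decisions$verdict
  if (length(verdict) == 0) stop_nirauth("empty decision set")
  if (length(verdict) != length(labels))
    stop_nirauth("decisions and labels differ in length")
  pos <- labels == "genuine"
  acc <- verdict == "genuine"
  TP <- sum(pos & acc); FN <- sum(pos & !acc)
  TN <- sum(!pos & !acc); FP <- sum(!pos & acc)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP,
                 sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
                 accuracy = (TP + TN) / length(verdict)),
            class = "one_class_report")
}

#' @export
print.one_class_report <- function(x, ...) {
  cat(sprintf("one-class report: sens %.3f / spec %.3f / acc %.3f (TP %d FN %d TN %d FP %d)\n",
              x$sensitivity, x$specificity, x$accuracy, x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Select the number of principal components on a validation set
#'
#' Fits one model per candidate on the genuine training spectra and picks
#' the candidate maximizing balanced accuracy
#' `(sensitivity + specificity) / 2` on the validation set; ties go to the
#' smallest candidate. The test set is never touched.
#'
#' @param train genuine training spectra (matrix).
#' @param val validation spectra (matrix) containing both classes.
#' @param val_labels validation labels (`"genuine"` vs anything else).
#' @param candidates integer vector of candidate component counts.
#' @param alpha,gamma significance levels passed to [dds_fit()].
#' @return list with `n_pc` (the winner), `score` (balanced accuracy per
#'   candidate) and `model` (the refitted winner).
#' @export
dds_select_n_pc <- function(train, val, val_labels, candidates = 1:10,
                            alpha = 0.01, gamma = 0.01) {
  pos <- val_labels == "genuine"
  if (!any(pos) || all(pos))
    stop_nirauth("validation set must contain both genuine and adulterated samples")
  score <- vapply(candidates, function(a) {
    m <- dds_fit(train, n_pc = a, alpha = alpha, gamma = gamma)
    r <- dds_evaluate(predict(m, val), val_labels)
    (r$sensitivity + r$specificity) / 2
  }, numeric(1))
  best <- candidates[which.max(score)]   # first max -> smallest candidate wins ties
  list(n_pc = best, score = stats::setNames(score, candidates),
       model = dds_fit(train, n_pc = best, alpha = alpha, gamma = gamma))
}

#' Serialize / restore a DD-SIMCA model as JSON
#' @param model a `dd_simca`.
#' @param path file path.
#' @return `dds_from_json` returns a `dd_simca`.
#' @export
dds_to_json <- function(model, path) {
  x <- list(n_pc = model$n_pc, alpha = model$alpha, gamma = model$gamma,
            h0 = model$h0, v0 = model$v0, N_h = model$N_h, N_v = model$N_v,
            c_crit = model$c_crit, c_out = model$c_out,
            n_train = model$n_train,
            mean = model$pca$mean,
            eigenvalues = model$pca$eigenvalues,
            loadings = model$pca$loadings)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname dds_to_json
#' @export
dds_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pca <- structure(list(mean = x$mean, loadings = as.matrix(x$loadings),
                        eigenvalues = x$eigenvalues, A = x$n_pc,
                        center = TRUE),
                   class = "pca_model")
  structure(list(pca = pca, n_pc = as.integer(x$n_pc), h0 = x$h0, v0 = x$v0,
                 N_h = as.integer(x$N_h), N_v = as.integer(x$N_v),
                 alpha = x$alpha, gamma = x$gamma, c_crit = x$c_crit,
                 c_out = x$c_out, n_train = x$n_train),
            class = "dd_simca")
}
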