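#' Specification of a baseline classifier
#'
#' Contract object for the supervised baselines. No mature classifier
#' libraries are assumed: all four estimators are implemented natively with
#' documented defaults -- a linear-kernel soft-margin SVM (C = 1, dual
#' coordinate descent), a CART decision tree (Gini impurity, no depth cap),
#' a single-hidden-layer neural network (25 logistic units, Adam, fixed
#' epoch budget, seeded initialisation), and Gaussian naive Bayes with
#' variance smoothing.
#'
#' @param kind one of `"DT"`, `"SVM"`, `"ANN"`, `"NB"`.
#' @param seed seed for any stochastic element (ANN initialisation, SVM
#'   epoch shuffling).
#' @param ... hyperparameter overrides: `C` (SVM), `hidden`, `epochs`,
#'   `learning_rate` (ANN), `min_split`, `max_depth` (DT), `var_smoothing`
#'   (NB).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("SVM", "DT", "ANN", "NB"), seed = 42L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    SVM = list(C = 1, max_epochs = 5000L, tol = 1e-6),
    DT = list(min_split = 2L, max_depth = 30L),
    ANN = list(hidden = 25L, epochs = 300L, learning_rate = 0.01),
    NB = list(var_smoothing = 1e-9))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, seed = as.integer(seed), hp = hp),
            class = "classifier_spec")
}

#' Fit / predict a baseline classifier
#' @param spec a [classifier_spec()].
#' @param X numeric training matrix (samples in rows).
#' @param labels training class labels (>= 2 classes).
#' @return `fit_classifier`: a fitted `classifier_fit`;
#'   `predict` returns a character label vector.
#' @export
fit_classifier <- function(spec, X, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_nirauth("training data contain a single class")
  fit <- switch(spec$kind,
    SVM = svm_linear_fit(X, labels, classes, spec$hp, spec$seed),
    DT = cart_fit(X, labels, classes, spec$hp),
    ANN = ann_fit(X, labels, classes, spec$hp, spec$seed),
    NB = nb_fit(X, labels, classes, spec$hp))
  structure(list(spec = spec, classes = classes, fit = fit),
            class = "classifier_fit")
}

#' @export
predict.classifier_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  switch(object$spec$kind,
    SVM = svm_linear_predict(object$fit, X, object$classes),
    DT = cart_predict(object$fit, X),
    ANN = ann_predict(object$fit, X, object$classes),
    NB = nb_predict(object$fit, X, object$classes))
}

## ---- linear SVM (dual coordinate descent, one-vs-rest) ---------------------

# L1-loss dual coordinate descent for a linear SVM with bias folded in as an
# extra constant feature; deterministic given the seed (seeded epoch order)
svm_binary <- function(X, y, C, max_epochs, tol, seed) {
  Xa <- cbind(X, 1)
  n <- nrow(Xa)
  qii <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  ord_all <- with_stage_seed(seed, "svm_order",
                             replicate(max_epochs, sample.int(n), simplify = FALSE))
  for (ep in seq_len(max_epochs)) {
    delta_max <- 0
    for (i in ord_all[[ep]]) {
      g <- y[i] * sum(w * Xa[i, ]) - 1
      pg <- if (alpha[i] == 0) min(g, 0) else if (alpha[i] == C) max(g, 0) else g
      if (pg != 0) {
        a_old <- alpha[i]
        alpha[i] <- min(max(alpha[i] - g / qii[i], 0), C)
        d <- (alpha[i] - a_old)
        if (d != 0) w <- w + d * y[i] * Xa[i, ]
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  w
}

svm_linear_fit <- function(X, labels, classes, hp, seed) {
  # features are z-scored from the training data (the usual SVM default) so
  # the soft margin is well conditioned regardless of absorbance scale
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  W <- if (length(classes) == 2) {
    y <- ifelse(labels == classes[2], 1, -1)
    matrix(svm_binary(Z, y, hp$C, hp$max_epochs, hp$tol, seed), ncol = 1)
  } else {
    sapply(classes, function(cl) {
      y <- ifelse(labels == cl, 1, -1)
      svm_binary(Z, y, hp$C, hp$max_epochs, hp$tol, seed)
    })
  }
  list(W = W, mu = mu, sdv = sdv)
}

svm_linear_predict <- function(fit, X, classes) {
  Z <- sweep(sweep(X, 2, fit$mu), 2, fit$sdv, `/`)
  scores <- cbind(Z, 1) %*% fit$W
  if (length(classes) == 2) {
    ifelse(as.vector(scores) > 0, classes[2], classes[1])
  } else {
    classes[max.col(scores, ties.method = "first")]
  }
}

## ---- Gaussian naive Bayes --------------------------------------------------

nb_fit <- function(X, labels, classes, hp) {
  stats <- lapply(classes, function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    list(mu = colMeans(Xi),
         var = apply(Xi, 2, stats::var),
         prior = nrow(Xi) / nrow(X))
  })
  allvar <- apply(X, 2, stats::var)
  eps <- hp$var_smoothing * max(allvar, 1e-30)
  for (k in seq_along(stats)) {
    v <- stats[[k]]$var
    v[is.na(v)] <- 0
    stats[[k]]$var <- v + eps
  }
  stats
}

nb_predict <- function(fit, X, classes) {
  ll <- sapply(fit, function(s) {
    -0.5 * rowSums(sweep(sweep(X, 2, s$mu)^2, 2, s$var, `/`)) -
      0.5 * sum(log(2 * pi * s$var)) + log(s$prior)
  })
  ll <- matrix(ll, nrow = nrow(X))
  classes[max.col(ll, ties.method = "first")]
}

## ---- CART decision tree ----------------------------------------------------

# best Gini split of one node; returns NULL when no split improves impurity
cart_best_split <- function(X, yi, n_class) {
  n <- length(yi)
  best <- list(gain = 0)
  parent_counts <- tabulate(yi, n_class)
  gini_parent <- 1 - sum((parent_counts / n)^2)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- yi[ord]
    cuts <- which(diff(xs) > 0)
    if (!length(cuts)) next
    left <- matrix(0, n, n_class)
    left[cbind(seq_len(n), ys)] <- 1
    left <- apply(left, 2, cumsum)
    nl <- seq_len(n)
    gl <- 1 - rowSums((left / nl)^2)
    right <- matrix(parent_counts, n, n_class, byrow = TRUE) - left
    nr <- n - nl
    gr <- 1 - rowSums((right / pmax(nr, 1))^2)
    gain <- gini_parent - (nl * gl + nr * gr) / n
    k <- cuts[which.max(gain[cuts])]
    if (gain[k] > best$gain + 1e-12) {
      best <- list(gain = gain[k], feature = j,
                   threshold = (xs[k] + xs[k + 1]) / 2)
    }
  }
  if (best$gain > 0) best else NULL
}

cart_grow <- function(X, yi, n_class, hp, depth = 0L) {
  counts <- tabulate(yi, n_class)
  leaf <- list(leaf = TRUE, class = which.max(counts))
  if (length(yi) < hp$min_split || depth >= hp$max_depth ||
      sum(counts > 0) == 1)
    return(leaf)
  sp <- cart_best_split(X, yi, n_class)
  if (is.null(sp)) return(leaf)
  go_left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = cart_grow(X[go_left, , drop = FALSE], yi[go_left], n_class,
                        hp, depth + 1L),
       right = cart_grow(X[!go_left, , drop = FALSE], yi[!go_left], n_class,
                         hp, depth + 1L))
}

cart_fit <- function(X, labels, classes, hp) {
  yi <- match(labels, classes)
  list(tree = cart_grow(X, yi, length(classes), hp), classes = classes)
}

cart_predict_one <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  node$class
}

cart_predict <- function(fit, X) {
  fit$classes[apply(X, 1, function(x) cart_predict_one(fit$tree, x))]
}

## ---- single-hidden-layer neural network ------------------------------------

ann_fit <- function(X, labels, classes, hp, seed) {
  # columns are z-scored from the training data for optimisation stability
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  Y <- one_hot(labels)
  n <- nrow(Z); p <- ncol(Z); h <- hp$hidden; k <- ncol(Y)
  init <- with_stage_seed(seed, "ann_init", {
    list(W1 = matrix(stats::rnorm(p * h, 0, 1 / sqrt(p)), p, h),
         W2 = matrix(stats::rnorm(h * k, 0, 1 / sqrt(h)), h, k))
  })
  W1 <- init$W1; b1 <- numeric(h); W2 <- init$W2; b2 <- numeric(k)
  # full-batch Adam on softmax cross-entropy
  mstate <- lapply(list(W1, b1, W2, b2), function(x) x * 0)
  vstate <- mstate
  beta1 <- 0.9; beta2 <- 0.999; epsd <- 1e-8; lr <- hp$learning_rate
  for (it in seq_len(hp$epochs)) {
    H <- 1 / (1 + exp(-(Z %*% W1 + matrix(b1, n, h, byrow = TRUE))))
    S <- H %*% W2 + matrix(b2, n, k, byrow = TRUE)
    S <- S - apply(S, 1, max)
    Pr <- exp(S); Pr <- Pr / rowSums(Pr)
    dS <- (Pr - Y) / n
    gW2 <- crossprod(H, dS); gb2 <- colSums(dS)
    dH <- dS %*% t(W2) * H * (1 - H)
    gW1 <- crossprod(Z, dH); gb1 <- colSums(dH)
    grads <- list(gW1, gb1, gW2, gb2)
    params <- list(W1, b1, W2, b2)
    for (pi in 1:4) {
      mstate[[pi]] <- beta1 * mstate[[pi]] + (1 - beta1) * grads[[pi]]
      vstate[[pi]] <- beta2 * vstate[[pi]] + (1 - beta2) * grads[[pi]]^2
      mh <- mstate[[pi]] / (1 - beta1^it)
      vh <- vstate[[pi]] / (1 - beta2^it)
      params[[pi]] <- params[[pi]] - lr * mh / (sqrt(vh) + epsd)
    }
    W1 <- params[[1]]; b1 <- params[[2]]; W2 <- params[[3]]; b2 <- params[[4]]
  }
  list(mu = mu, sdv = sdv, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

ann_predict <- function(fit, X, classes) {
  Z <- sweep(sweep(X, 2, fit$mu), 2, fit$sdv, `/`)
  n <- nrow(Z)
  H <- 1 / (1 + exp(-(Z %*% fit$W1 + matrix(fit$b1, n, length(fit$b1), byrow = TRUE))))
  S <- H %*% fit$W2 + matrix(fit$b2, n, length(fit$b2), byrow = TRUE)
  classes[max.col(S, ties.method = "first")]
}

## ---- evaluation ------------------------------------------------------------

#' Confusion matrix report
#'
#' @param true,pred character label vectors of equal length.
#' @return a `confusion_report`: `matrix` (rows = true classes),
#'   `per_class` accuracy, `accuracy` (trace / total).
#' @export
confusion_report <- function(true, pred) {
  if (length(true) != length(pred)) stop_nirauth("length mismatch")
  if (length(true) == 0) stop_nirauth("empty input")
  classes <- sort(unique(c(true, pred)))
  m <- table(factor(true, classes), factor(pred, classes))
  structure(list(matrix = unclass(m),
                 per_class = diag(unclass(m)) / pmax(rowSums(m), 1),
                 accuracy = sum(diag(unclass(m))) / length(true)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("confusion report: overall accuracy %.3f\n", x$accuracy))
  print(x$matrix)
  invisible(x)
}

#' Stratified K-fold cross-validation of a classifier
#'
#' Folds are stratified by class and seeded. Out-of-fold predictions are
#' pooled into a single confusion matrix.
#'
#' @param spec a [classifier_spec()].
#' @param X feature matrix.
#' @param labels class labels; every class needs at least `folds` members.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return a `confusion_report`.
#' @export
crossval_classifier <- function(spec, X, labels, folds = 10L, seed = 42L) {
  X <- as.matrix(X); labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < folds))
    stop_nirauth("class '", names(counts)[which.min(counts)], "' has ",
                 min(counts), " members < ", folds,
                 " folds; use fewer folds")
  assign_fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    perm <- with_stage_seed(seed, paste0("cv_", cl), sample(idx))
    assign_fold[perm] <- rep_len(seq_len(folds), length(idx))
  }
  pred <- character(length(labels))
  for (f in seq_len(folds)) {
    te <- assign_fold == f
    fit <- fit_classifier(spec, X[!te, , drop = FALSE], labels[!te])
    pred[te] <- predict(fit, X[te, , drop = FALSE])
  }
  confusion_report(labels, pred)
}

#' Hold-out evaluation of a classifier
#'
#' Fits on the training indices and evaluates once on the disjoint test
#' indices.
#'
#' @param spec a [classifier_spec()].
#' @param X feature matrix covering both subsets.
#' @param labels class labels.
#' @param train_idx,test_idx disjoint row indices.
#' @return a `confusion_report` on the test subset.
#' @export
holdout_eval <- function(spec, X, labels, train_idx, test_idx) {
  if (length(intersect(train_idx, test_idx)))
    stop_nirauth("train and test indices overlap")
  X <- as.matrix(X)
  fit <- fit_classifier(spec, X[train_idx, , drop = FALSE], labels[train_idx])
  confusion_report(labels[test_idx],
                   predict(fit, X[test_idx, , drop = FALSE]))
}
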