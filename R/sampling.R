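#' Kennard-Stone representative sample selection
#'
#' Deterministic maximin selection: the first two picks are the mutually
#' farthest pair (Euclidean distance); every later pick maximizes its minimum
#' distance to the already-selected set. Ties are broken by the lowest index,
#' so the ordering is fully deterministic.
#'
#' @param X numeric matrix, samples in rows.
#' @param k number of samples to select, `2 <= k <= nrow(X)`.
#' @return integer vector of `k` selected row indices, in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2 || k > n) stop_nirauth("k must satisfy 2 <= k <= n (k=", k, ", n=", n, ")")
  D <- as.matrix(stats::dist(X))
  if (max(D) == 0)
    stop_nirauth("degenerate distance matrix: all samples identical")
  # first pair: maximal distance, row-major scan for lowest-index tie-break
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sel <- as.integer(idx[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)               # which.max takes the first maximum
    sel <- c(sel, as.integer(nxt))
    mind <- pmin(mind, D[, nxt])
  }
  unname(sel)
}

new_split <- function(train, val, test, scheme) {
  structure(list(train_idx = sort(train), val_idx = sort(val),
                 test_idx = sort(test), scheme = scheme),
            class = "sample_split")
}

#' @export
print.sample_split <- function(x, ...) {
  cat(sprintf("%s Kennard-Stone split: train %d / val %d / test %d\n",
              x$scheme, length(x$train_idx), length(x$val_idx),
              length(x$test_idx)))
  invisible(x)
}

#' Kennard-Stone data splits (6:2:2 and 7:3 schemes)
#'
#' `split_622` partitions into training / validation / test at 60/20/20:
#' KS selects the training set from all samples, then KS on the remainder
#' selects the validation set; the residue is the test set. If `labels` are
#' supplied the split is stratified: KS runs independently within each class
#' so every subset contains every class. `split_73` selects a 70% calibration
#' set; the residue is the prediction set.
#'
#' @param X numeric matrix, samples in rows.
#' @param labels optional per-sample class labels for stratification.
#' @return a `sample_split` with disjoint sorted index sets covering
#'   `1:nrow(X)`; `split_73` has an empty `val_idx`.
#' @export
split_622 <- function(X, labels = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop_nirauth("need at least 5 samples for a 6:2:2 split")
  if (is.null(labels)) labels <- rep("all", n)
  stopifnot(length(labels) == n)
  parts <- lapply(split(seq_len(n), labels), function(idx) {
    nc <- length(idx)
    if (nc < 5) stop_nirauth("stratum with ", nc, " samples is too small to split 6:2:2")
    n_train <- round(0.6 * nc); n_val <- round(0.2 * nc)
    tr <- kennard_stone(X[idx, , drop = FALSE], n_train)
    rest <- idx[-tr]
    va <- kennard_stone(X[rest, , drop = FALSE], n_val)
    list(train = idx[tr], val = rest[va], test = rest[-va])
  })
  new_split(unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
            unlist(lapply(parts, `[[`, "val"), use.names = FALSE),
            unlist(lapply(parts, `[[`, "test"), use.names = FALSE),
            "6:2:2")
}

#' @rdname split_622
#' @export
split_73 <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop_nirauth("need at least 5 samples for a 7:3 split")
  n_cal <- round(0.7 * n)
  cal <- kennard_stone(X, n_cal)
  new_split(cal, integer(0), setdiff(seq_len(n), cal), "7:3")
}
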