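#' Wavenumber grid for FT-NIR spectra
#'
#' Constructs the uniform, strictly decreasing wavenumber axis on which all
#' spectra in the package live. The default mirrors an FT-NIR instrument
#' scanning 10,000 to 4,000 cm^-1 at 8 cm^-1 resolution, digitised to 1557
#' points, so the spacing is 6000/1556 cm^-1.
#'
#' @param n_points number of grid points (default 1557).
#' @param high,low first and last wavenumber in cm^-1 (defaults 10,000 and
#'   4,000). `high` must exceed `low`.
#' @return an object of class `wn_grid` with fields `values` (descending
#'   wavenumbers) and `n_points`.
#' @export
wn_grid <- function(n_points = 1557L, high = 10000, low = 4000) {
  stopifnot(n_points >= 2, high > low)
  g <- structure(
    list(values = seq(high, low, length.out = n_points), n_points = as.integer(n_points)),
    class = "wn_grid")
  g
}

# signed grid spacing (negative: wavenumbers descend with index)
wn_spacing <- function(grid) {
  (grid$values[grid$n_points] - grid$values[1]) / (grid$n_points - 1)
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("wavenumber grid: %d points, %.1f .. %.1f cm^-1 (spacing %.4f)\n",
              x$n_points, x$values[1], x$values[x$n_points], abs(wn_spacing(x))))
  invisible(x)
}

#' Container for a set of NIR spectra with sample metadata
#'
#' The universal currency of the pipeline: a samples-by-wavenumbers absorbance
#' matrix in log(1/R) absorbance units, together with per-sample class labels,
#' adulterant mass fractions, batch ids and (for mixtures and pure
#' adulterants) the adulterant identity.
#'
#' @param grid a [wn_grid()].
#' @param absorbance numeric matrix, `n` samples by `grid$n_points`.
#' @param label character, per-sample class: `"genuine"`, `"adulterated"`, or
#'   a pure-adulterant class name.
#' @param fraction numeric in `[0, 1]`: adulterant mass fraction. Must be 0
#'   for genuine samples and 1 for pure adulterants.
#' @param batch integer batch id per sample (0 = no batch structure).
#' @param adulterant character, adulterant class name per sample (`NA` for
#'   genuine samples).
#' @param sample_id optional character ids; generated if missing.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(grid, absorbance, label, fraction,
                        batch = rep(0L, nrow(absorbance)),
                        adulterant = rep(NA_character_, nrow(absorbance)),
                        sample_id = NULL) {
  stopifnot(inherits(grid, "wn_grid"), is.matrix(absorbance))
  n <- nrow(absorbance)
  if (ncol(absorbance) != grid$n_points)
    stop_nirauth("absorbance has ", ncol(absorbance), " columns but grid has ",
                 grid$n_points, " points")
  if (!all(is.finite(absorbance)))
    stop_nirauth("absorbance matrix contains non-finite values")
  if (length(label) != n || length(fraction) != n || length(batch) != n ||
      length(adulterant) != n)
    stop_nirauth("metadata length does not match number of spectra (", n, ")")
  if (any(fraction < 0 | fraction > 1))
    stop_nirauth("fractions must lie in [0, 1]")
  if (any(label == "genuine" & fraction != 0))
    stop_nirauth("genuine samples must have fraction 0")
  if (any(label != "genuine" & label != "adulterated" & fraction != 1))
    stop_nirauth("pure adulterant samples must have fraction 1")
  if (is.null(sample_id)) sample_id <- sprintf("s%03d", seq_len(n))
  structure(list(grid = grid, absorbance = absorbance,
                 label = as.character(label), fraction = as.numeric(fraction),
                 batch = as.integer(batch), adulterant = as.character(adulterant),
                 sample_id = as.character(sample_id)),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d points\n",
              nrow(x$absorbance), x$grid$n_points))
  tab <- table(x$label)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i) {
  spectra_set(x$grid, x$absorbance[i, , drop = FALSE], x$label[i],
              x$fraction[i], x$batch[i], x$adulterant[i], x$sample_id[i])
}

#' Number of spectra in a set
#' @param set a `spectra_set`.
#' @return integer sample count.
#' @export
n_spectra <- function(set) nrow(set$absorbance)

#' Write / read a spectra set as a wide CSV
#'
#' Wide layout: metadata columns `sample_id,label,adulterant,fraction,batch`
#' followed by one column per wavenumber, the header carrying the wavenumber
#' value. Values round-trip at full double precision.
#'
#' @param set a [spectra_set()].
#' @param path file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a `spectra_set`.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  df <- data.table::data.table(
    sample_id = set$sample_id, label = set$label, adulterant = set$adulterant,
    fraction = set$fraction, batch = set$batch)
  ab <- data.table::as.data.table(set$absorbance)
  data.table::setnames(ab, format(set$grid$values, digits = 10, trim = TRUE,
                                  scientific = FALSE))
  data.table::fwrite(cbind(df, ab), path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop_nirauth("file not found: ", path)
  if (file.size(path) == 0) stop_nirauth("empty file: ", path)
  dt <- data.table::fread(path, header = TRUE, check.names = FALSE,
                          fill = FALSE)
  meta_cols <- c("sample_id", "label", "adulterant", "fraction", "batch")
  if (!all(meta_cols %in% names(dt)))
    stop_nirauth("missing metadata columns: ",
                 paste(setdiff(meta_cols, names(dt)), collapse = ", "))
  if (nrow(dt) == 0) stop_nirauth("empty file: ", path, " (no sample rows)")
  wn_names <- setdiff(names(dt), meta_cols)
  wn <- suppressWarnings(as.numeric(wn_names))
  if (any(is.na(wn)))
    stop_nirauth("non-numeric wavenumber header at column ",
                 which(is.na(wn))[1] + length(meta_cols))
  if (any(diff(wn) >= 0))
    stop_nirauth("wavenumber header not strictly decreasing at column ",
                 which(diff(wn) >= 0)[1] + length(meta_cols))
  ab <- as.matrix(dt[, wn_names, with = FALSE])
  if (!is.numeric(ab)) {
    bad <- which(!vapply(dt[, wn_names, with = FALSE], is.numeric, TRUE))[1]
    stop_nirauth("non-numeric absorbance value in column ", wn_names[bad])
  }
  dimnames(ab) <- NULL
  grid <- structure(list(values = wn, n_points = length(wn)), class = "wn_grid")
  spectra_set(grid, ab, dt$label, dt$fraction, dt$batch, dt$adulterant,
              dt$sample_id)
}
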