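#' Descriptor elimination and scaling
#'
#' Before model building, descriptors that are mostly zero or nearly constant
#' are eliminated, and the survivors are min-max scaled to `[-1, 1]` using
#' statistics fitted on training rows only (the libsvm convention).
#'
#' @name preprocess
NULL

filter_report <- function(removed_sparse = character(0),
                          removed_low_variation = character(0),
                          zero_fraction = NA_real_, rel_sd = NA_real_) {
  structure(list(removed_by_sparsity = removed_sparse,
                 removed_by_low_variation = removed_low_variation,
                 zero_fraction = zero_fraction, rel_sd = rel_sd),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d removed by sparsity (> %.0f%% zeros), %d by low variation (SD/range < %s)\n",
              length(x$removed_by_sparsity), 100 * x$zero_fraction,
              length(x$removed_by_low_variation),
              format(x$rel_sd)))
  invisible(x)
}

#' Remove mostly-zero descriptors
#'
#' Drops every column whose fraction of exact zeros is strictly greater than
#' `zero_fraction` ("more than 80% zero values" at the default). Zero testing
#' uses exact equality by default (Dragon-style tables carry literal zeros);
#' set `eps > 0` to treat `|x| < eps` as zero.
#'
#' @param dm Numeric descriptor matrix (compounds x descriptors).
#' @param zero_fraction Threshold in (0, 1); default 0.8.
#' @param eps Absolute tolerance for the zero test; default 0 (exact).
#' @return List with `matrix` (columns retained, rows unchanged) and `report`
#'   (a `filter_report`).
#' @export
filter_sparse <- function(dm, zero_fraction = 0.8, eps = 0) {
  check_matrix(dm)
  stopifnot(zero_fraction > 0, zero_fraction < 1)
  zf <- if (eps > 0) colMeans(abs(dm) < eps) else colMeans(dm == 0)
  removed <- colnames(dm)[zf > zero_fraction]
  keep <- setdiff(colnames(dm), removed)
  if (!length(keep))
    stop("sparsity filter removed every descriptor", call. = FALSE)
  list(matrix = dm[, keep, drop = FALSE],
       report = filter_report(removed_sparse = removed,
                              zero_fraction = zero_fraction))
}

#' Remove near-constant descriptors
#'
#' Drops columns whose sample standard deviation relative to the column range
#' (max - min) is below `rel_sd` ("standard deviation less than 3%" read as a
#' unit-free ratio); constant columns (range 0) are always dropped.
#'
#' @param dm Numeric descriptor matrix.
#' @param rel_sd Threshold on SD/range; default 0.03.
#' @return List with `matrix` and `report`.
#' @export
filter_low_variation <- function(dm, rel_sd = 0.03) {
  check_matrix(dm)
  rng <- apply(dm, 2, function(x) diff(range(x)))
  sds <- apply(dm, 2, stats::sd)
  removed <- colnames(dm)[rng == 0 | (rng > 0 & sds / pmax(rng, .Machine$double.xmin) < rel_sd)]
  keep <- setdiff(colnames(dm), removed)
  if (!length(keep))
    stop("low-variation filter removed every descriptor", call. = FALSE)
  list(matrix = dm[, keep, drop = FALSE],
       report = filter_report(removed_low_variation = removed, rel_sd = rel_sd))
}

#' Apply both elimination rules in the fixed order
#'
#' Sparsity first, then low variation; the order is recorded in the merged
#' report.
#'
#' @inheritParams filter_sparse
#' @inheritParams filter_low_variation
#' @return List with `matrix` and merged `report`.
#' @export
filter_descriptors <- function(dm, zero_fraction = 0.8, rel_sd = 0.03, eps = 0) {
  s <- filter_sparse(dm, zero_fraction, eps)
  v <- filter_low_variation(s$matrix, rel_sd)
  list(matrix = v$matrix,
       report = filter_report(
         removed_sparse = s$report$removed_by_sparsity,
         removed_low_variation = v$report$removed_by_low_variation,
         zero_fraction = zero_fraction, rel_sd = rel_sd))
}

#' Fit min-max scaling parameters on training rows
#'
#' Each column's minimum and maximum over the training rows define an affine
#' map onto `[-1, 1]`. Test and external rows may map outside the interval;
#' no clipping is done.
#'
#' @param dm Numeric descriptor matrix.
#' @param rows Compound ids of the training rows; default all rows.
#' @param fitted_on Identifier of the fitting set, kept for audit.
#' @return Object of class `scaling_params` with per-column `center`
#'   ((min+max)/2) and `halfwidth` ((max-min)/2).
#' @export
fit_scaling <- function(dm, rows = rownames(dm), fitted_on = "training") {
  check_matrix(dm)
  missing <- setdiff(rows, rownames(dm))
  if (length(missing))
    stop("training rows not in matrix: ", paste(utils::head(missing, 5),
                                                collapse = ", "), call. = FALSE)
  x <- dm[rows, , drop = FALSE]
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  if (any(maxs == mins))
    stop("column(s) constant on the training rows (zero scale): ",
         paste(utils::head(colnames(dm)[maxs == mins], 5), collapse = ", "),
         "; run the low-variation filter per split", call. = FALSE)
  structure(list(center = (mins + maxs) / 2, halfwidth = (maxs - mins) / 2,
                 columns = colnames(dm), fitted_on = fitted_on),
            class = "scaling_params")
}

#' Apply (or invert) fitted scaling
#'
#' @param dm Numeric descriptor matrix whose columns were all present when the
#'   parameters were fitted.
#' @param sp A `scaling_params` object from [fit_scaling()].
#' @return Matrix of the same shape, affinely mapped to the scaled space.
#' @export
apply_scaling <- function(dm, sp) {
  check_matrix(dm)
  stopifnot(inherits(sp, "scaling_params"))
  unknown <- setdiff(colnames(dm), sp$columns)
  if (length(unknown))
    stop("no scaling parameters for column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cols <- colnames(dm)
  sweep(sweep(dm, 2, sp$center[cols]), 2, sp$halfwidth[cols], "/")
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(dm, sp) {
  check_matrix(dm)
  stopifnot(inherits(sp, "scaling_params"))
  cols <- colnames(dm)
  sweep(sweep(dm, 2, sp$halfwidth[cols], "*"), 2, sp$center[cols], "+")
}
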