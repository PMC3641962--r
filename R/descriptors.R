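#' Molecular descriptors of the final BCRP substrate model
#'
#' The selected substrate-classification model uses five descriptors: the mean
#' information index on atomic composition (AAC), spherosity (SPH), two
#' mass-weighted 3D-MoRSE signals (Mor17m, Mor25m), and the mass-weighted
#' GETAWAY R autocorrelation of lag 2 (R2m). These are computed natively from
#' 3D structures following the standard descriptor-handbook definitions;
#' arbitrary further descriptors enter the pipeline through
#' [load_descriptor_table()]. Values will not match commercial Dragon output
#' bit-for-bit (Dragon's exact implementation is unpublished), but each
#' definition used here is stated precisely below.
#'
#' @name native-descriptors
NULL

# Carbon-scaled atomic weights: w_i = 1 (unit) or mass_i / mass_C (mass).
descriptor_weights <- function(m, weighting = c("mass", "unit")) {
  weighting <- match.arg(weighting)
  if (weighting == "unit") rep(1, n_atoms(m))
  else m$atoms$mass / ATOMIC_MASSES[["C"]]
}

require_3d <- function(m, what) {
  if (!isTRUE(m$three_d))
    stop(what, " requires 3D coordinates, but '", m$name,
         "' is 2D-only (e.g. built from SMILES); supply a 3D structure",
         call. = FALSE)
}

#' Mean information index on atomic composition (AAC)
#'
#' Shannon entropy, in bits, of the molecule's element-count distribution:
#' \eqn{-\sum_g (n_g/n) \log_2 (n_g/n)} over element types \eqn{g}. Hydrogens
#' count as atoms. A purely geometric-free composition index.
#'
#' @param m A [molecule()].
#' @return AAC in bits, in `[0, log2(number of element types)]`.
#' @examples
#' ch4 <- toy_molecules()$structures[["methane"]]
#' aac(ch4)  # entropy of (1/5, 4/5) = 0.7219 bits
#' @export
aac <- function(m) {
  p <- table(m$atoms$element) / n_atoms(m)
  -sum(p * log2(p))
}

#' Spherosity (SPH)
#'
#' Shape index from the eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge
#' \lambda_3} of the covariance matrix of atom-centered coordinates:
#' \eqn{3\lambda_3 / (\lambda_1+\lambda_2+\lambda_3)}. 0 for planar or linear
#' arrangements, 1 for spherically isotropic ones. Unweighted (geometric)
#' covariance.
#'
#' @param m A [molecule()] with at least 2 non-coincident atoms.
#' @return Spherosity in `[0, 1]`.
#' @export
spherosity <- function(m) {
  require_3d(m, "spherosity")
  if (n_atoms(m) < 2)
    stop("spherosity needs at least 2 atoms", call. = FALSE)
  x <- coordinates(m)
  cv <- stats::cov(x)
  tr <- sum(diag(cv))
  if (tr <= .Machine$double.eps)
    stop("degenerate geometry: all atoms coincide, spherosity undefined",
         call. = FALSE)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  3 * max(ev[3], 0) / tr
}

#' 3D-MoRSE signal
#'
#' Electron-diffraction-inspired scattering sum over atom pairs:
#' \eqn{\mathrm{Mor}(s) = \sum_{i<j} w_i w_j \sin(s r_{ij}) / (s r_{ij})},
#' with the summand defined as \eqn{w_i w_j} when \eqn{s r_{ij} = 0}.
#' The Dragon signal index k corresponds to scattering parameter
#' `s = k - 1` (per Angstrom), so Mor17m and Mor25m are `s = 16` and `s = 24`
#' with mass weighting.
#'
#' @param m A [molecule()] with 3D coordinates.
#' @param s Scattering parameter, 1/Angstrom, `s >= 0`.
#' @param weighting `"mass"` (atomic mass / carbon mass) or `"unit"`.
#' @return The signal value (0 for a single atom: empty pair sum).
#' @export
morse_signal <- function(m, s, weighting = c("mass", "unit")) {
  require_3d(m, "3D-MoRSE")
  if (s < 0) stop("scattering parameter s must be >= 0", call. = FALSE)
  n <- n_atoms(m)
  if (n < 2) return(0)
  w <- descriptor_weights(m, weighting)
  r <- interatomic_distances(m)
  iu <- which(upper.tri(r), arr.ind = TRUE)
  sr <- s * r[iu]
  sinc <- ifelse(sr == 0, 1, sin(sr) / sr)
  sum(w[iu[, 1]] * w[iu[, 2]] * sinc)
}

#' GETAWAY R autocorrelation
#'
#' Combines atomic leverages from the molecular influence matrix
#' \eqn{H = M (M^T M)^{-1} M^T} (M = atom-centered coordinates) with geometry
#' and topology:
#' \eqn{R_{lag} = \sum_{i<j,\, d_{topo}(i,j)=lag} \sqrt{h_i h_j} / r_{ij}
#' \cdot w_i w_j}. For planar or linear geometries (rank-deficient
#' \eqn{M^T M}) the Moore-Penrose pseudo-inverse is used; the result then
#' carries attribute `pseudo_inverse = TRUE`.
#'
#' @param m A [molecule()] with a connected bond graph and 3D coordinates.
#' @param lag Topological distance at which pairs are collected, `>= 1`.
#' @param weighting `"mass"` or `"unit"`.
#' @return Non-negative autocorrelation value; 0 when no atom pair sits at
#'   the requested lag.
#' @export
getaway_r_autocorrelation <- function(m, lag = 2L, weighting = c("mass", "unit")) {
  require_3d(m, "GETAWAY R autocorrelation")
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1", call. = FALSE)
  n <- n_atoms(m)
  if (n < lag + 1)
    stop("GETAWAY R autocorrelation of lag ", lag, " needs at least ",
         lag + 1, " atoms", call. = FALSE)
  M <- scale(coordinates(m), center = TRUE, scale = FALSE)
  G <- crossprod(M)
  pseudo <- FALSE
  if (abs(det(G)) < 1e-10 * max(1, sum(diag(G))^3)) {
    Ginv <- MASS::ginv(G)
    pseudo <- TRUE
  } else {
    Ginv <- solve(G)
  }
  h <- pmax(rowSums((M %*% Ginv) * M), 0)
  dt <- topological_distances(m)
  r <- interatomic_distances(m)
  w <- descriptor_weights(m, weighting)
  iu <- which(upper.tri(dt) & dt == lag, arr.ind = TRUE)
  if (nrow(iu) == 0) return(structure(0, pseudo_inverse = pseudo))
  val <- sum(sqrt(h[iu[, 1]] * h[iu[, 2]]) / r[iu] * w[iu[, 1]] * w[iu[, 2]])
  structure(val, pseudo_inverse = pseudo)
}

# Registry of natively computable descriptors, named as in Dragon.
native_descriptor_list <- function() {
  list(
    AAC    = function(m) aac(m),
    SPH    = function(m) spherosity(m),
    Mor17m = function(m) morse_signal(m, s = 16, weighting = "mass"),
    Mor25m = function(m) morse_signal(m, s = 24, weighting = "mass"),
    R2m    = function(m) as.numeric(getaway_r_autocorrelation(m, lag = 2L,
                                                              weighting = "mass"))
  )
}

#' Names of the natively computable descriptors
#' @return Character vector: `AAC`, `SPH`, `Mor17m`, `Mor25m`, `R2m`.
#' @export
native_descriptors <- function() names(native_descriptor_list())

#' Build a descriptor matrix
#'
#' Constructs the pipeline's central table: compounds (rows) by named
#' real-valued descriptors (columns), with per-column provenance recording
#' whether a value was computed natively or ingested from an external table.
#'
#' @param values Numeric matrix with compound ids as row names and descriptor
#'   names as column names; all values finite.
#' @param provenance Either a single string applied to all columns or a named
#'   character vector per column (`"computed"` or `"ingested"`).
#' @return The matrix with class `descriptor_matrix` and attribute
#'   `provenance`.
#' @export
descriptor_matrix <- function(values, provenance = "computed") {
  check_matrix(values)
  if (length(provenance) == 1)
    provenance <- stats::setNames(rep(provenance, ncol(values)), colnames(values))
  stopifnot(all(colnames(values) %in% names(provenance)))
  structure(values, provenance = provenance[colnames(values)],
            class = c("descriptor_matrix", class(values)))
}

#' Compute descriptors for a compound set
#'
#' @param cs A [compound_set()] whose structures are [molecule()] objects.
#' @param descriptors Character vector of native descriptor names
#'   (see [native_descriptors()]).
#' @param on_error `"abort"` stops at the first per-compound failure (naming
#'   the compound); `"drop"` drops the failing compound's row and records it
#'   in attribute `dropped`.
#' @return A [descriptor_matrix()] with provenance `"computed"`.
#' @export
compute_descriptor_matrix <- function(cs,
                                      descriptors = native_descriptors(),
                                      on_error = c("abort", "drop")) {
  on_error <- match.arg(on_error)
  stopifnot(inherits(cs, "compound_set"))
  reg <- native_descriptor_list()
  unknown <- setdiff(descriptors, names(reg))
  if (length(unknown))
    stop("not natively computable: ", paste(unknown, collapse = ", "),
         "; ingest them with load_descriptor_table()", call. = FALSE)
  rows <- list()
  dropped <- character(0)
  for (id in cs$ids) {
    v <- tryCatch(
      vapply(descriptors, function(d) reg[[d]](cs$structures[[id]]), numeric(1)),
      error = function(e) e)
    if (inherits(v, "error")) {
      if (on_error == "abort")
        stop("descriptor computation failed for compound '", id, "': ",
             conditionMessage(v), call. = FALSE)
      dropped <- c(dropped, id)
    } else {
      rows[[id]] <- v
    }
  }
  if (!length(rows))
    stop("descriptor computation failed for every compound", call. = FALSE)
  values <- do.call(rbind, rows)
  colnames(values) <- descriptors
  out <- descriptor_matrix(values, "computed")
  attr(out, "dropped") <- dropped
  out
}

#' Load a precomputed (Dragon-style) descriptor table
#'
#' Delimited text (comma or tab), first column the compound id, remaining
#' header names the descriptors.
#'
#' @param path Path to the table.
#' @param missing Policy for non-numeric or missing cells: `"abort"` (default,
#'   error listing offending cells), `"drop_row"`, or `"drop_column"`; drops
#'   are recorded in attributes `dropped_rows` / `dropped_columns`.
#' @return A [descriptor_matrix()] with provenance `"ingested"`.
#' @export
load_descriptor_table <- function(path,
                                  missing = c("abort", "drop_row", "drop_column")) {
  missing <- match.arg(missing)
  df <- read_delim_sniff(path)
  if (ncol(df) < 2)
    stop("descriptor table needs an id column plus at least one descriptor",
         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate compound id in descriptor table: ",
         ids[duplicated(ids)][1], call. = FALSE)
  if (anyDuplicated(names(df)[-1]))
    stop("duplicated descriptor column header: ",
         names(df)[-1][duplicated(names(df)[-1])][1], call. = FALSE)
  values <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(ids, names(df)[-1]))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  dropped_rows <- character(0); dropped_cols <- character(0)
  if (nrow(bad)) {
    cells <- paste0(rownames(values)[bad[, 1]], ":", colnames(values)[bad[, 2]])
    if (missing == "abort") {
      stop("non-numeric or missing cells in descriptor table: ",
           paste(utils::head(cells, 10), collapse = ", "), call. = FALSE)
    } else if (missing == "drop_row") {
      dropped_rows <- unique(rownames(values)[bad[, 1]])
      values <- values[!rownames(values) %in% dropped_rows, , drop = FALSE]
    } else {
      dropped_cols <- unique(colnames(values)[bad[, 2]])
      values <- values[, !colnames(values) %in% dropped_cols, drop = FALSE]
    }
    if (!nrow(values) || !ncol(values))
      stop("missing-value policy removed every row/column", call. = FALSE)
  }
  out <- descriptor_matrix(values, "ingested")
  attr(out, "dropped_rows") <- dropped_rows
  attr(out, "dropped_columns") <- dropped_cols
  out
}

#' Write a descriptor matrix to delimited text
#'
#' Tab-separated, first column `id`; a plain-text `key: value` provenance
#' sidecar is written next to it (`<path>.provenance`).
#'
#' @param dm Descriptor matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_descriptor_table <- function(dm, path) {
  check_matrix(dm)
  df <- data.frame(id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- attr(dm, "provenance")
  if (!is.null(prov))
    writeLines(paste0(names(prov), ": ", prov), paste0(path, ".provenance"))
  invisible(path)
}
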