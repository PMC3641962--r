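#' Specification of a synthetic two-class descriptor dataset
#'
#' Describes the statistical structure the classification pipeline assumes:
#' informative descriptors whose class means are shifted by `delta`
#' within-class standard deviations, class-independent noise descriptors,
#' near-duplicate columns that the correlation pruner must remove,
#' zero-inflated columns that the sparsity filter must remove, and an
#' optional borderline fraction of compounds whose informative profile sits
#' midway between the classes (mimicking the region where substrates and
#' non-substrates are structurally too similar to separate). Defaults mirror
#' the modelling conditions of the BCRP data set: 164 substrates, 99
#' non-substrates, a handful of genuinely informative descriptors among many
#' uninformative ones, and a class-mean separation of 3 SD units.
#'
#' @param n_pos,n_neg Compounds per class (substrate / non-substrate).
#' @param n_informative Number of class-shifted descriptors.
#' @param n_noise Number of class-independent descriptors.
#' @param delta Class-mean shift of informative descriptors, in within-class
#'   SD units (>= 0).
#' @param n_correlated_duplicates Near-copies of informative descriptors
#'   (jittered so that |r| > 0.99).
#' @param n_zero_inflated Columns carrying a planted fraction of exact zeros.
#' @param zero_fraction Exact-zero fraction of the zero-inflated columns.
#' @param borderline_fraction Fraction of compounds drawn from the midpoint
#'   mixture of the two classes (they keep their true label, creating
#'   irreducible error by construction).
#' @param seed RNG seed; the generated matrix is a deterministic function of
#'   the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 164, n_neg = 99, n_informative = 5,
                           n_noise = 95, delta = 3,
                           n_correlated_duplicates = 0, n_zero_inflated = 0,
                           zero_fraction = 0.9, borderline_fraction = 0,
                           seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_informative >= 0, n_noise >= 0,
            delta >= 0, n_correlated_duplicates >= 0, n_zero_inflated >= 0,
            zero_fraction > 0, zero_fraction < 1,
            borderline_fraction >= 0, borderline_fraction < 1)
  if (n_pos + n_neg == 0) stop("zero compounds requested", call. = FALSE)
  if (n_informative + n_noise + n_correlated_duplicates + n_zero_inflated == 0)
    stop("zero descriptors requested", call. = FALSE)
  if (n_correlated_duplicates > 0 && n_informative == 0)
    stop("correlated duplicates require informative columns to copy",
         call. = FALSE)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic descriptor dataset with known ground truth
#'
#' Informative columns are unit-variance normal draws with class means at
#' `+delta/2` (substrate) and `-delta/2` (non-substrate); noise columns are
#' standard normal for both classes; duplicate columns are near-copies of
#' informative columns (class signal attenuated to 95%, plus N(0, 0.03)
#' jitter, keeping |r| > 0.99 with the source); zero-inflated columns carry
#' exactly `round(zero_fraction * n)` zeros with strictly positive values
#' elsewhere.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (a [descriptor_matrix()]), `labels` (named
#'   character), `informative`, `duplicates`, `zero_inflated` (column names),
#'   `borderline` (row ids), and `spec`.
#' @export
make_descriptor_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_pos + spec$n_neg
  ids <- sprintf("cmpd%04d", seq_len(n))
  labels <- stats::setNames(
    c(rep(LABEL_SUBSTRATE, spec$n_pos), rep(LABEL_NONSUBSTRATE, spec$n_neg)),
    ids)
  sign_shift <- ifelse(labels == LABEL_SUBSTRATE, 0.5, -0.5) * spec$delta
  with_seed(spec$seed, {
    borderline <- sort(sample.int(n, round(spec$borderline_fraction * n)))
    mu <- sign_shift
    mu[borderline] <- 0  # midpoint mixture: no class shift for these rows
    cols <- list()
    if (spec$n_informative > 0) {
      inf_names <- sprintf("INF%02d", seq_len(spec$n_informative))
      for (nm in inf_names) cols[[nm]] <- stats::rnorm(n, mean = mu, sd = 1)
    } else inf_names <- character(0)
    if (spec$n_noise > 0) {
      for (nm in sprintf("NOI%02d", seq_len(spec$n_noise)))
        cols[[nm]] <- stats::rnorm(n)
    }
    dup_names <- character(0)
    if (spec$n_correlated_duplicates > 0) {
      dup_names <- sprintf("DUP%02d", seq_len(spec$n_correlated_duplicates))
      src <- rep_len(inf_names, spec$n_correlated_duplicates)
      # duplicates are slightly attenuated copies (95% of the class signal,
      # plus jitter): still |r| > 0.99 with the source, but the original is
      # always the more discriminative member of the pair
      for (k in seq_along(dup_names))
        cols[[dup_names[k]]] <- cols[[src[k]]] - 0.05 * mu +
          stats::rnorm(n, sd = 0.03)
    }
    zero_names <- character(0)
    if (spec$n_zero_inflated > 0) {
      zero_names <- sprintf("ZER%02d", seq_len(spec$n_zero_inflated))
      n_zero <- round(spec$zero_fraction * n)
      for (nm in zero_names) {
        v <- abs(stats::rnorm(n)) + 0.5
        v[sample.int(n, n_zero)] <- 0
        cols[[nm]] <- v
      }
    }
    values <- do.call(cbind, cols)
  })
  rownames(values) <- ids
  list(matrix = descriptor_matrix(values, "computed"),
       labels = labels,
       informative = inf_names,
       duplicates = dup_names,
       zero_inflated = zero_names,
       borderline = ids[borderline],
       spec = spec)
}

#' Fixed toy molecules with exact coordinates
#'
#' A small, versioned set of molecules with hand-specified geometries used as
#' descriptor fixtures: methane (ideal tetrahedral), water (ideal bent),
#' ethane (staggered), benzene (planar regular hexagon), carbon dioxide
#' (linear), plus two branched 12-atom molecules (isobutene and propan-2-ol).
#' Labels are arbitrary fixed assignments so the set can exercise labeled
#' pipelines end to end.
#'
#' @return A [compound_set()] of seven molecules.
#' @export
toy_molecules <- function() {
  t_len <- 1.09 / sqrt(3)  # C-H bond 1.09 A along tetrahedral directions
  methane <- molecule(
    c("C", "H", "H", "H", "H"),
    rbind(c(0, 0, 0),
          t_len * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))),
    cbind(1, 2:5), name = "methane")

  # water: O-H 0.9572 A, H-O-H 104.52 degrees, in the xy plane
  ang <- 104.52 * pi / 180
  water <- molecule(
    c("O", "H", "H"),
    rbind(c(0, 0, 0), c(0.9572, 0, 0),
          0.9572 * c(cos(ang), sin(ang), 0)),
    rbind(c(1, 2), c(1, 3)), name = "water")

  ethane <- molecule(
    c("C", "C", "H", "H", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.54, 0, 0),
          c(-0.36, 1.03, 0), c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89),
          c(1.90, 1.03, 0), c(1.90, -0.51, -0.89), c(1.90, -0.51, 0.89)),
    rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6), c(2, 7), c(2, 8)),
    name = "ethane")

  # benzene: regular hexagon, C at 1.396 A, H at 2.479 A, strictly planar
  th <- (0:5) * pi / 3
  benzene <- molecule(
    c(rep("C", 6), rep("H", 6)),
    rbind(cbind(1.396 * cos(th), 1.396 * sin(th), 0),
          cbind(2.479 * cos(th), 2.479 * sin(th), 0)),
    rbind(cbind(1:6, c(2:6, 1), rep(c(1L, 2L), 3)),
          cbind(1:6, 7:12, 1L)),
    name = "benzene")

  co2 <- molecule(
    c("C", "O", "O"),
    rbind(c(0, 0, 0), c(0, 0, 1.16), c(0, 0, -1.16)),
    rbind(c(1, 2, 2), c(1, 3, 2)), name = "carbon dioxide")

  # isobutene (2-methylpropene), 12 atoms, approximate sp2/sp3 geometry
  isobutene <- molecule(
    c("C", "C", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H"),
    rbind(c(0.00, 0.00, 0.00),    # C1 =CH2
          c(1.33, 0.00, 0.00),    # C2 central sp2
          c(2.08, 1.28, 0.05),    # C3 methyl
          c(2.10, -1.26, -0.05),  # C4 methyl
          c(-0.55, 0.92, 0.03), c(-0.56, -0.93, -0.03),
          c(1.52, 2.17, 0.30), c(2.89, 1.18, 0.78), c(2.55, 1.48, -0.92),
          c(1.55, -2.16, -0.28), c(2.92, -1.15, 0.67), c(2.56, -1.47, -1.03)),
    rbind(c(1, 2, 2), c(2, 3, 1), c(2, 4, 1),
          c(1, 5, 1), c(1, 6, 1),
          c(3, 7, 1), c(3, 8, 1), c(3, 9, 1),
          c(4, 10, 1), c(4, 11, 1), c(4, 12, 1)),
    name = "isobutene")

  # propan-2-ol, 12 atoms, branched at C2
  propan2ol <- molecule(
    c("C", "C", "C", "O", "H", "H", "H", "H", "H", "H", "H", "H"),
    rbind(c(-1.26, -0.46, 0.12),  # C1
          c(0.00, 0.35, 0.00),    # C2
          c(1.27, -0.48, 0.05),   # C3
          c(0.02, 1.29, 1.08),    # O
          c(-1.31, -1.17, -0.71), c(-2.15, 0.17, 0.06), c(-1.27, -0.99, 1.07),
          c(0.01, 0.93, -0.93),
          c(2.16, 0.15, -0.02), c(1.30, -1.17, -0.80), c(1.32, -1.05, 0.98),
          c(0.84, 1.78, 1.05)),
    rbind(c(1, 2, 1), c(2, 3, 1), c(2, 4, 1),
          c(1, 5, 1), c(1, 6, 1), c(1, 7, 1),
          c(2, 8, 1),
          c(3, 9, 1), c(3, 10, 1), c(3, 11, 1),
          c(4, 12, 1)),
    name = "propan-2-ol")

  mols <- list(methane = methane, water = water, ethane = ethane,
               benzene = benzene, co2 = co2, isobutene = isobutene,
               propan2ol = propan2ol)
  labels <- stats::setNames(
    c("substrate", "non-substrate", "substrate", "non-substrate",
      "non-substrate", "substrate", "substrate"),
    names(mols))
  compound_set(mols, labels, provenance = "fixed toy-molecule fixtures")
}

#' Modelling / external split of compound ids
#'
#' Partitions a labeled compound pool into a modelling set and an external
#' validation set of stated sizes, preserving the class proportions
#' (deterministic proportional allocation, remainder to the modelling set).
#' With the defaults this reproduces the 263 = 223 modelling (139 substrate /
#' 84 non-substrate) + 40 external (25/15) layout.
#'
#' @param labels Named character vector of class labels for all compounds.
#' @param n_external Number of compounds to hold out; default 40.
#' @param seed Seed for sampling which compounds go external.
#' @return List with `modelling` and `external` id vectors (disjoint,
#'   exhaustive).
#' @export
make_split_fixture <- function(labels, n_external = 40, seed = 1) {
  labels <- check_labels(labels)
  n <- length(labels)
  if (n_external >= n)
    stop("external set must be smaller than the compound pool", call. = FALSE)
  ids <- names(labels)
  ext <- character(0)
  if (n_external > 0) {
    classes <- unique(labels)
    quota <- round(n_external * table(labels)[classes] / n)
    # rounding can leave the quota one short/long of the requested size
    excess <- sum(quota) - n_external
    if (excess != 0) quota[1] <- quota[1] - excess
    with_seed(seed, {
      for (cl in classes) {
        pool <- ids[labels == cl]
        ext <- c(ext, pool[sample.int(length(pool), quota[[cl]])])
      }
    })
  }
  list(modelling = setdiff(ids, ext), external = sort(ext))
}
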