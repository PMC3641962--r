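#' Construct a molecule
#'
#' A minimal molecule model: element symbols with standard atomic masses,
#' 3D coordinates in Angstroms, and an undirected bond graph. This is all the
#' descriptor engine needs; no charges, valence or stereochemistry are kept.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstroms.
#' @param bonds Two- or three-column matrix or data frame of bonds:
#'   atom index i, atom index j (1-based), and optionally an integer bond
#'   order (default 1).
#' @param name Display name.
#' @param three_d Logical; `FALSE` marks structures that carry only layout
#'   (2D) coordinates, e.g. those materialized from SMILES. 3D descriptors
#'   refuse such molecules.
#' @return An object of class `molecule` with components `atoms` (data frame:
#'   element, mass, x, y, z), `bonds` (data frame: i, j, order), `name`, and
#'   `three_d`.
#' @examples
#' water <- molecule(c("O", "H", "H"),
#'                   rbind(c(0, 0, 0), c(0.9572, 0, 0),
#'                         c(-0.2400, 0.9266, 0)),
#'                   rbind(c(1, 2), c(1, 3)), name = "water")
#' n_atoms(water)
#' @export
molecule <- function(elements, coords, bonds = NULL, name = "", three_d = TRUE) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1) stop("a molecule needs at least one atom", call. = FALSE)
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix matching the atom count", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("atomic coordinates must be finite", call. = FALSE)
  mass <- atomic_mass(elements)

  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    if (ncol(bonds) == 2) bonds$order <- 1L
    bonds <- bonds[, 1:3]
    names(bonds) <- c("i", "j", "order")
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond references a non-existent atom index", call. = FALSE)
    if (any(bonds$i == bonds$j))
      stop("self-bonds are not allowed", call. = FALSE)
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key))
      stop("duplicate bond between the same atom pair", call. = FALSE)
    if (any(bonds$order < 1))
      stop("bond order must be a positive integer", call. = FALSE)
  }

  structure(
    list(atoms = data.frame(element = elements, mass = mass,
                            x = coords[, 1], y = coords[, 2], z = coords[, 3]),
         bonds = bonds, name = name, three_d = isTRUE(three_d)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds%s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds),
              if (x$three_d) "" else " [2D-only]"))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param m A [molecule()].
#' @return Integer atom count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Atomic coordinates of a molecule
#' @param m A [molecule()].
#' @return Numeric n x 3 matrix of coordinates in Angstroms.
#' @export
coordinates <- function(m) {
  as.matrix(m$atoms[, c("x", "y", "z")])
}

adjacency_list <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

bfs_component <- function(adj, start) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

#' Topological (bond-count) distance matrix
#'
#' Minimum number of bonds between every pair of atoms, by breadth-first
#' search over the bond graph. Needed by descriptors defined on a fixed
#' topological lag, such as the GETAWAY R autocorrelation.
#'
#' @param m A [molecule()] with a connected bond graph.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
topological_distances <- function(m) {
  n <- n_atoms(m)
  adj <- adjacency_list(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    di <- bfs_component(adj, i)
    if (anyNA(di))
      stop("bond graph is disconnected (e.g. a salt with a counter-ion); ",
           "use largest_fragment() to keep the largest covalent fragment",
           call. = FALSE)
    d[i, ] <- di
  }
  d
}

#' Interatomic (Euclidean) distance matrix
#'
#' @param m A [molecule()].
#' @return Symmetric numeric matrix of pairwise distances in Angstroms.
#' @export
interatomic_distances <- function(m) {
  as.matrix(stats::dist(coordinates(m)))
}

#' Keep the largest covalent fragment of a disconnected structure
#'
#' Splits the bond graph into connected components and keeps the component
#' with the most atoms (ties broken by the component containing the
#' lowest-numbered atom). Opt-in handling for salts and co-crystals; the
#' descriptor engine otherwise refuses disconnected structures.
#'
#' @param m A [molecule()].
#' @return A [molecule()] restricted to the largest fragment, atom order
#'   preserved.
#' @export
largest_fragment <- function(m) {
  n <- n_atoms(m)
  adj <- adjacency_list(m)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[!is.na(bfs_component(adj, i))] <- cid
    }
  }
  sizes <- tabulate(comp, nbins = cid)
  keep_id <- which(sizes == max(sizes))[1]
  keep <- which(comp == keep_id)
  idx_map <- match(seq_len(n), keep)
  b <- m$bonds[m$bonds$i %in% keep & m$bonds$j %in% keep, , drop = FALSE]
  molecule(m$atoms$element[keep], coordinates(m)[keep, , drop = FALSE],
           data.frame(i = idx_map[b$i], j = idx_map[b$j], order = b$order),
           name = m$name, three_d = m$three_d)
}
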