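# Shared fixtures and independent oracles used across test files.

# Drop names and attributes (e.g. the `decision` attribute on predictions).
unattr <- function(x) {
  attributes(x) <- NULL
  x
}

# Write a minimal V2000 SDF with given atoms/bonds and return the path.
write_test_sdf <- function(records, path = tempfile(fileext = ".sdf")) {
  lines <- character(0)
  for (rec in records) {
    at <- rec$atoms   # data.frame: element, x, y, z
    bd <- rec$bonds   # matrix: i, j, order
    lines <- c(lines,
               rec$name, "  test", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), NROW(bd)),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0", at$x, at$y, at$z,
                       at$element),
               if (NROW(bd)) sprintf("%3d%3d%3d  0", bd[, 1], bd[, 2], bd[, 3]),
               "M  END", "$$$$")
  }
  writeLines(lines, path)
  path
}

ethane_record <- function() {
  list(name = "ethane",
       atoms = data.frame(
         element = c("C", "C", "H", "H", "H", "H", "H", "H"),
         x = c(0, 1.54, -0.36, -0.36, -0.36, 1.90, 1.90, 1.90),
         y = c(0, 0, 1.03, -0.51, -0.51, 1.03, -0.51, -0.51),
         z = c(0, 0, 0, 0.89, -0.89, 0, -0.89, 0.89)),
       bonds = cbind(c(1, 1, 1, 1, 2, 2, 2), c(2, 3, 4, 5, 6, 7, 8), 1))
}

methane_record <- function() {
  t_len <- 1.09 / sqrt(3)
  list(name = "methane",
       atoms = data.frame(
         element = c("C", "H", "H", "H", "H"),
         x = t_len * c(0, 1, 1, -1, -1),
         y = t_len * c(0, 1, -1, 1, -1),
         z = t_len * c(0, 1, -1, -1, 1)),
       bonds = cbind(1, 2:5, 1))
}

# Random rigid transform: rotation (QR-orthogonalized Gaussian, det +1) plus
# translation, applied to a molecule's coordinates.
random_rigid_transform <- function(m, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3, sd = 5)
  xyz <- sweep(coordinates(m) %*% Q, 2, shift, "+")
  molecule(m$atoms$element, xyz, m$bonds, name = m$name, three_d = m$three_d)
}

# Permute atom order (remapping bonds) without changing the molecule.
permute_atoms <- function(m, perm) {
  inv <- order(perm)
  b <- m$bonds
  molecule(m$atoms$element[perm], coordinates(m)[perm, , drop = FALSE],
           data.frame(i = inv[b$i], j = inv[b$j], order = b$order),
           name = m$name, three_d = m$three_d)
}

# Independent brute-force descriptor oracles: direct double-loop evaluation
# of the defining formulas, sharing no code with the implementations.

oracle_aac <- function(m) {
  counts <- table(m$atoms$element)
  n <- sum(counts)
  tot <- 0
  for (g in names(counts)) {
    p <- counts[[g]] / n
    tot <- tot - p * log(p) / log(2)
  }
  tot
}

oracle_spherosity <- function(m) {
  xyz <- coordinates(m)
  centered <- sweep(xyz, 2, colMeans(xyz))
  cv <- t(centered) %*% centered / (nrow(xyz) - 1)
  ev <- sort(eigen(cv)$values, decreasing = TRUE)
  3 * ev[3] / sum(ev)
}

oracle_morse <- function(m, s, mass_weighted = TRUE) {
  w <- if (mass_weighted) m$atoms$mass / 12.011 else rep(1, n_atoms(m))
  xyz <- coordinates(m)
  n <- nrow(xyz)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        term <- if (s * r == 0) 1 else sin(s * r) / (s * r)
        tot <- tot + w[i] * w[j] * term
      }
    }
  }
  tot
}

# All-pairs shortest path by Floyd-Warshall over the bond graph.
oracle_topo_dist <- function(m) {
  n <- n_atoms(m)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(m$bonds))) {
    d[m$bonds$i[k], m$bonds$j[k]] <- 1
    d[m$bonds$j[k], m$bonds$i[k]] <- 1
  }
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_getaway_r <- function(m, lag, mass_weighted = TRUE) {
  w <- if (mass_weighted) m$atoms$mass / 12.011 else rep(1, n_atoms(m))
  xyz <- coordinates(m)
  M <- sweep(xyz, 2, colMeans(xyz))
  H <- M %*% MASS::ginv(t(M) %*% M) %*% t(M)
  h <- pmax(diag(H), 0)
  dt <- oracle_topo_dist(m)
  n <- nrow(xyz)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && dt[i, j] == lag) {
        r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        tot <- tot + sqrt(h[i] * h[j]) / r * w[i] * w[j]
      }
    }
  }
  tot
}

# Brute-force application of the correlation-pruning rule: walk candidates
# in descending F-score, drop any candidate correlated at >= threshold with
# an already-kept one.
oracle_prune <- function(dm, scores, thr) {
  ord <- scores$descriptor
  kept <- character(0)
  for (cand in ord) {
    ok <- TRUE
    for (k in kept) {
      if (abs(cor(dm[, cand], dm[, k])) >= thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, cand)
  }
  kept
}

# Small labeled random feature matrix for SVM/selection tests.
random_instance <- function(n = 40, d = 3, delta = 2, seed = 1) {
  set.seed(seed)
  n_pos <- ceiling(n / 2)
  labels <- c(rep("substrate", n_pos), rep("non-substrate", n - n_pos))
  x <- matrix(rnorm(n * d), n, d)
  x[, 1] <- x[, 1] + ifelse(labels == "substrate", delta / 2, -delta / 2)
  dimnames(x) <- list(sprintf("c%02d", seq_len(n)), sprintf("f%02d", seq_len(d)))
  list(x = x, labels = stats::setNames(labels, rownames(x)))
}

# Columns with an exact target sample correlation matrix: center, make the
# columns orthonormal, then impose the Cholesky factor of R.
exact_correlation_matrix <- function(n, R, seed = 1) {
  set.seed(seed)
  d <- nrow(R)
  X <- matrix(rnorm(n * d), n, d)
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))
  Y <- Q %*% chol(R)
  scale(Y)  # unit variance, exact correlation R
}
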