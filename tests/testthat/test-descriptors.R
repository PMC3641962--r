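tm <- toy_molecules()

test_that("AAC equals the Shannon entropy of the element composition", {
  o2 <- molecule(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 1.21)),
                 rbind(c(1, 2, 2)))
  expect_equal(aac(o2), 0)
  # methane: entropy of (1/5, 4/5); water: entropy of (1/3, 2/3)
  expect_equal(aac(tm$structures$methane),
               -(1 / 5 * log2(1 / 5) + 4 / 5 * log2(4 / 5)))
  expect_equal(round(aac(tm$structures$methane), 4), 0.7219)
  expect_equal(round(aac(tm$structures$water), 4), 0.9183)
})

test_that("spherosity separates planar, linear and isotropic geometries", {
  expect_equal(spherosity(tm$structures$benzene), 0)
  expect_equal(spherosity(tm$structures$co2), 0)  # collinear
  # regular tetrahedron: isotropic covariance, all eigenvalues equal
  tetra <- molecule(rep("C", 4),
                    rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                    rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(spherosity(tetra), 1, tolerance = 1e-12)
  expect_gte(spherosity(tm$structures$propan2ol), 0)
  expect_lte(spherosity(tm$structures$propan2ol), 1)

  coincident <- molecule(c("C", "C"), rbind(c(1, 1, 1), c(1, 1, 1)),
                         rbind(c(1, 2)))
  expect_error(spherosity(coincident), "degenerate")
})

test_that("3D-MoRSE signal follows the sinc-sum definition", {
  # two atoms, unit weights, r = 1.5, s = 16 -> sin(24)/24
  two <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                  rbind(c(1, 2)))
  expect_equal(morse_signal(two, 16, weighting = "unit"), sin(24) / 24)

  single <- molecule("C", matrix(0, 1, 3))
  expect_equal(morse_signal(single, 16), 0)

  # s = 0: every sinc term is 1, so the sum is sum_{i<j} w_i w_j
  for (m in tm$structures[c("water", "ethane", "benzene")]) {
    w <- m$atoms$mass / 12.011
    pairs <- combn(length(w), 2)
    expect_equal(morse_signal(m, 0, weighting = "mass"),
                 sum(w[pairs[1, ]] * w[pairs[2, ]]))
  }
  expect_error(morse_signal(two, -1), "s must be")
})

test_that("GETAWAY R autocorrelation matches a hand-coded influence-matrix oracle", {
  water <- tm$structures$water
  # lag 2 in water is the single H..H pair: sqrt(h_H h_H) / r_HH * w_H^2
  M <- scale(coordinates(water), center = TRUE, scale = FALSE)
  H <- M %*% MASS::ginv(t(M) %*% M) %*% t(M)
  h <- diag(H)
  r_hh <- sqrt(sum((coordinates(water)[2, ] - coordinates(water)[3, ])^2))
  w_h <- 1.008 / 12.011
  expect_equal(as.numeric(getaway_r_autocorrelation(water, 2)),
               sqrt(h[2] * h[3]) / r_hh * w_h^2,
               tolerance = 1e-12, ignore_attr = TRUE)
  # no pair at lag 3 in methane (max topological distance 2)
  expect_equal(as.numeric(getaway_r_autocorrelation(tm$structures$methane, 3)), 0)
  expect_error(getaway_r_autocorrelation(tm$structures$water, 3), "at least 4")
})

test_that("native descriptors agree with brute-force formula oracles on all fixtures", {
  for (m in tm$structures) {
    expect_equal(aac(m), oracle_aac(m), tolerance = 1e-9, info = m$name)
    if (n_atoms(m) >= 2)
      expect_equal(spherosity(m), oracle_spherosity(m), tolerance = 1e-9,
                   info = m$name)
    expect_equal(morse_signal(m, 16), oracle_morse(m, 16), tolerance = 1e-9,
                 info = m$name)
    expect_equal(morse_signal(m, 24), oracle_morse(m, 24), tolerance = 1e-9,
                 info = m$name)
    if (n_atoms(m) >= 3)
      expect_equal(as.numeric(getaway_r_autocorrelation(m, 2)),
                   oracle_getaway_r(m, 2), tolerance = 1e-9, info = m$name)
  }
})

test_that("all five descriptors are invariant under rigid rotation and translation", {
  for (m in tm$structures[c("water", "ethane", "benzene", "isobutene", "propan2ol")]) {
    ref <- c(aac(m), spherosity(m), morse_signal(m, 16), morse_signal(m, 24),
             as.numeric(getaway_r_autocorrelation(m, 2)))
    for (s in 1:20) {
      mt <- random_rigid_transform(m, seed = 1000 + s)
      got <- c(aac(mt), spherosity(mt), morse_signal(mt, 16),
               morse_signal(mt, 24), as.numeric(getaway_r_autocorrelation(mt, 2)))
      expect_equal(got, ref, tolerance = 1e-9)
    }
  }
})

test_that("descriptors are invariant under atom reordering", {
  for (m in tm$structures[c("water", "ethane", "propan2ol")]) {
    set.seed(11)
    for (rep in 1:3) {
      perm <- sample(n_atoms(m))
      mp <- permute_atoms(m, perm)
      expect_equal(aac(mp), aac(m))
      expect_equal(morse_signal(mp, 16), morse_signal(m, 16), tolerance = 1e-12)
      expect_equal(as.numeric(getaway_r_autocorrelation(mp, 2)),
                   as.numeric(getaway_r_autocorrelation(m, 2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("unit-weight MoRSE is bounded by the number of atom pairs", {
  for (m in tm$structures) {
    n <- n_atoms(m)
    if (n < 2) next
    for (s in c(1, 8, 16, 24))
      expect_lte(abs(morse_signal(m, s, weighting = "unit")), choose(n, 2))
  }
})

test_that("descriptor matrices assemble with exact Dragon-style column names", {
  dm <- compute_descriptor_matrix(tm)
  expect_identical(colnames(dm), c("AAC", "SPH", "Mor17m", "Mor25m", "R2m"))
  expect_equal(nrow(dm), 7)
  expect_true(all(is.finite(dm)))
  expect_true(all(attr(dm, "provenance") == "computed"))

  small <- compound_set(tm$structures[c("water", "ethane", "benzene")],
                        tm$labels[c("water", "ethane", "benzene")])
  dm2 <- compute_descriptor_matrix(small, descriptors = c("AAC", "SPH"))
  expect_equal(dim(dm2), c(3, 2))
})

test_that("2D-only compounds abort or drop per the failure policy", {
  skip_if_not_installed("ChemmineOB")
  flat <- smiles_to_molecule("CCO", name = "ethanol")
  mixed <- compound_set(list(water = tm$structures$water, flat = flat),
                        c(water = "substrate", flat = "non-substrate"))
  expect_error(compute_descriptor_matrix(mixed), "flat")
  dm <- compute_descriptor_matrix(mixed, on_error = "drop")
  expect_equal(rownames(dm), "water")
  expect_equal(attr(dm, "dropped"), "flat")
})

test_that("descriptor tables load with missing-cell policies", {
  path <- tempfile(fileext = ".tsv")
  set.seed(3)
  vals <- matrix(round(rnorm(40), 4), 4, 10,
                 dimnames = list(paste0("c", 1:4), paste0("D", 1:10)))
  write.table(data.frame(id = rownames(vals), vals), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  dm <- load_descriptor_table(path)
  expect_equal(dim(dm), c(4, 10))
  expect_true(all(attr(dm, "provenance") == "ingested"))
  expect_equal(unname(dm[2, 3]), vals[2, 3])

  lines <- readLines(path)
  lines[3] <- sub("^(c2\t[^\t]*)\t[^\t]*", "\\1\tNA", lines[3])
  writeLines(lines, path)
  expect_error(load_descriptor_table(path), "c2:D2")
  dm <- load_descriptor_table(path, missing = "drop_column")
  expect_equal(attr(dm, "dropped_columns"), "D2")
  expect_equal(ncol(dm), 9)
  dm <- load_descriptor_table(path, missing = "drop_row")
  expect_equal(attr(dm, "dropped_rows"), "c2")

  writeLines(c("id\tD1\tD1", "c1\t1\t2"), path)
  expect_error(load_descriptor_table(path), "duplicated descriptor")
})

test_that("descriptor tables round-trip through write_descriptor_table", {
  dm <- compute_descriptor_matrix(tm)
  path <- tempfile(fileext = ".tsv")
  write_descriptor_table(dm, path)
  back <- load_descriptor_table(path)
  expect_equal(unclass(back), unclass(dm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(file.exists(paste0(path, ".provenance")))
})
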