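# Small synthetic problem + coarse grids keep the orchestration tests fast;
# the full-scale protocol is exercised in the acceptance suite.
small_problem <- function(seed = 1, delta = 3) {
  ds <- make_descriptor_dataset(synthetic_spec(n_pos = 40, n_neg = 26,
                                               n_informative = 3, n_noise = 9,
                                               delta = delta, seed = seed))
  sp <- make_split_fixture(ds$labels, n_external = 16, seed = seed)
  list(dm = ds$matrix[sp$modelling, ], labels = ds$labels[sp$modelling],
       ext_dm = ds$matrix[sp$external, ], ext_labels = ds$labels[sp$external],
       informative = ds$informative)
}
coarse <- list(C_grid = 2^seq(-3, 7, 2), gamma_grid = 2^seq(-7, 1, 2))

test_that("random splits have the documented sizes and reproducibility", {
  ids <- sprintf("c%03d", 1:223)
  sp <- random_split(ids, 0.75, seed = 4)
  expect_length(sp$train, 167)
  expect_length(sp$test, 56)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)

  sp2 <- random_split(ids, 0.75, seed = 4)
  expect_identical(sp, sp2)
  expect_false(identical(sp, random_split(ids, 0.75, seed = 5)))

  half <- random_split(sprintf("x%02d", 1:10), 0.5, seed = 1)
  expect_length(half$train, 5)
  expect_error(random_split("only-one", 0.5), "at least 2")

  labels <- setNames(rep(c("substrate", "non-substrate"), c(139, 84)), ids)
  st <- random_split(ids, 0.75, seed = 2, stratified = TRUE, labels = labels)
  expect_equal(sum(labels[st$train] == "substrate") / 139, 0.75,
               tolerance = 1 / 139)
  expect_equal(sum(labels[st$train] == "non-substrate") / 84, 0.75,
               tolerance = 1 / 84)
})

test_that("the protocol is deterministic given the base seed", {
  pb <- small_problem(seed = 6)
  run_once <- function() {
    run_protocol(pb$dm, pb$labels, pb$ext_dm, pb$ext_labels, n_runs = 3,
                 seed = 11, C_grid = coarse$C_grid,
                 gamma_grid = coarse$gamma_grid)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$means, b$means)
  expect_identical(serialize(a$runs, NULL), serialize(b$runs, NULL))
  expect_equal(length(a$runs), 3)
  # per-run bookkeeping: disjoint split, features from the matrix, reports
  r <- a$runs[[1]]
  expect_length(intersect(r$split$train, r$split$test), 0)
  expect_true(all(r$features %in% colnames(pb$dm)))
  expect_s3_class(r$reports$external, "performance_report")
})

test_that("external labels never influence model building (leakage audit)", {
  pb <- small_problem(seed = 9)
  scrambled <- setNames(sample(pb$ext_labels), names(pb$ext_labels))
  a <- run_protocol(pb$dm, pb$labels, pb$ext_dm, pb$ext_labels, n_runs = 2,
                    seed = 3, C_grid = coarse$C_grid,
                    gamma_grid = coarse$gamma_grid)
  b <- run_protocol(pb$dm, pb$labels, pb$ext_dm, scrambled, n_runs = 2,
                    seed = 3, C_grid = coarse$C_grid,
                    gamma_grid = coarse$gamma_grid)
  for (k in seq_along(a$runs)) {
    expect_identical(a$runs[[k]]$features, b$runs[[k]]$features)
    expect_identical(a$runs[[k]]$cost, b$runs[[k]]$cost)
    expect_identical(a$runs[[k]]$gamma, b$runs[[k]]$gamma)
    expect_identical(a$runs[[k]]$split, b$runs[[k]]$split)
    expect_identical(a$runs[[k]]$reports$training, b$runs[[k]]$reports$training)
    expect_identical(a$runs[[k]]$reports$test, b$runs[[k]]$reports$test)
    expect_identical(serialize(a$runs[[k]]$model, NULL),
                     serialize(b$runs[[k]]$model, NULL))
  }
  expect_false(identical(a$means[a$means$category == "external", ],
                         b$means[b$means$category == "external", ]))
})

test_that("informative features beat pure noise on held-out accuracy", {
  acc_signal <- acc_noise <- numeric(0)
  for (s in 1:4) {
    sig <- small_problem(seed = 20 + s, delta = 3)
    nul <- small_problem(seed = 20 + s, delta = 0)
    a <- run_protocol(sig$dm, sig$labels, n_runs = 2, seed = s,
                      C_grid = coarse$C_grid, gamma_grid = coarse$gamma_grid)
    b <- run_protocol(nul$dm, nul$labels, n_runs = 2, seed = s,
                      C_grid = coarse$C_grid, gamma_grid = coarse$gamma_grid)
    acc_signal <- c(acc_signal, a$means$acc[a$means$category == "test"])
    acc_noise <- c(acc_noise, b$means$acc[b$means$category == "test"])
  }
  expect_gt(mean(acc_signal), mean(acc_noise))
})

scripted_run <- function(run, acc_train, acc_test, n_features,
                         acc_external = NA) {
  structure(list(
    run = run,
    features = sprintf("f%02d", seq_len(n_features)),
    reports = list(
      training = structure(list(acc = acc_train), class = "performance_report"),
      test = structure(list(acc = acc_test), class = "performance_report"),
      external = structure(list(acc = acc_external), class = "performance_report"))),
    class = "run_record")
}

test_that("model selection minimizes the train/test gap, then the feature count", {
  runs <- list(scripted_run(1, 90, 81, 5),    # gap 9
               scripted_run(2, 85, 83.5, 8),  # gap 1.5, 8 features
               scripted_run(3, 84, 82.5, 4))  # gap 1.5, 4 features -> winner
  best <- select_best_model(runs)[[1]]
  expect_equal(best$run, 3)

  single <- select_best_model(runs[1])
  expect_equal(single[[1]]$run, 1)

  # permuting the run order changes nothing but documented index tie-breaks
  perm <- select_best_model(runs[c(2, 3, 1)])[[1]]
  expect_equal(perm$run, 3)

  # exhaustive-enumeration oracle over random scripted runs
  set.seed(33)
  for (rep in 1:10) {
    rr <- lapply(1:10, function(i)
      scripted_run(i, runif(1, 70, 100), runif(1, 60, 95), sample(3:12, 1)))
    got <- select_best_model(rr)[[1]]$run
    keys <- t(sapply(rr, function(r)
      c(abs(r$reports$training$acc - r$reports$test$acc), length(r$features),
        r$run)))
    want <- keys[order(keys[, 1], keys[, 2], keys[, 3])[1], 3]
    expect_equal(got, want)
  }
})

test_that("external accuracy is ignored by the selection rule", {
  runs <- list(scripted_run(1, 90, 88, 5, acc_external = 10),
               scripted_run(2, 90, 80, 5, acc_external = 100))
  expect_equal(select_best_model(runs)[[1]]$run, 1)
})

test_that("overlap matrices are symmetric with a 100 diagonal", {
  pb <- small_problem(seed = 14, delta = 4)
  pr <- run_protocol(pb$dm, pb$labels, n_runs = 3, seed = 5,
                     C_grid = coarse$C_grid, gamma_grid = coarse$gamma_grid)
  models <- lapply(pr$runs, function(r) r$model)
  om <- overlap_matrix(models, pb$dm)
  expect_equal(dim(om), c(3, 3))
  expect_true(all(diag(om) == 100))
  expect_identical(matrix(om, 3), t(matrix(om, 3)))
  expect_true(all(om >= 0 & om <= 100))
  s <- attr(om, "summary")
  expect_equal(unname(s["min"]), min(om[upper.tri(om)]))

  # a duplicated model always agrees with itself
  om2 <- overlap_matrix(list(m1 = models[[1]], m2 = models[[1]]), pb$dm)
  expect_equal(unname(om2[1, 2]), 100)
  # strongly separable data: every model predicts the planted truth
  expect_true(all(om[upper.tri(om)] > 90))
  expect_error(overlap_matrix(models[1], pb$dm), "at least 2")
})

test_that("end-to-end compound prediction echoes descriptors and the tie rules", {
  tm <- toy_molecules()
  dm <- compute_descriptor_matrix(tm)
  sp <- fit_scaling(dm)
  xs <- apply_scaling(dm, sp)
  model <- svm_train(xs, tm$labels, cost = 10,
                     kernel = kernel_spec("rbf", gamma = 0.5), scaling = sp)

  train_pred <- predict(model, xs)
  res <- predict_compound(model, tm$structures$methane)
  expect_equal(res$label, unname(train_pred["methane"]))
  expect_equal(res$AAC, unname(dm["methane", "AAC"]))

  batch <- predict_compound(model, tm$structures[c("water", "ethane", "co2")])
  expect_equal(nrow(batch), 3)
  expect_true(all(batch$label %in% c("substrate", "non-substrate")))

  # model files drive prediction the same way
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  res2 <- predict_compound(path, tm$structures$methane)
  expect_equal(res2$label, res$label)
  expect_equal(res2$decision, res$decision, tolerance = 1e-12)

  skip_if_not_installed("ChemmineOB")
  expect_error(predict_compound(model, "((((not-smiles"), "unparseable")
  # 2D-only SMILES structures are refused by a 3D-descriptor model
  expect_error(predict_compound(model, "CCO"), "2D-only")
})

test_that("kernel comparison and ratio sweeps have the published table shapes", {
  pb <- small_problem(seed = 18)
  ck <- compare_kernels(pb$dm, pb$labels, pb$ext_dm, pb$ext_labels,
                        n_runs = 2, seed = 2, C_grid = coarse$C_grid,
                        gamma_grid = coarse$gamma_grid)
  expect_equal(nrow(ck), 9)  # 3 kernels x 3 categories
  expect_setequal(unique(ck$kernel), c("linear", "polynomial", "rbf"))
  expect_setequal(unique(ck$category), c("training", "test", "external"))

  sr <- sweep_ratios(pb$dm, pb$labels, pb$ext_dm, pb$ext_labels,
                     fractions = c(0.6, 0.75), n_runs = 2, seed = 2,
                     C_grid = coarse$C_grid, gamma_grid = coarse$gamma_grid)
  expect_equal(nrow(sr), 6)  # 2 fractions x 3 categories
  # larger training fraction -> larger training sets actually used
  res <- attr(sr, "results")
  n_train <- sapply(res, function(p) length(p$runs[[1]]$split$train))
  expect_true(all(diff(n_train) > 0))
  # reruns with the same seeds give identical tables
  sr2 <- sweep_ratios(pb$dm, pb$labels, pb$ext_dm, pb$ext_labels,
                      fractions = c(0.6, 0.75), n_runs = 2, seed = 2,
                      C_grid = coarse$C_grid, gamma_grid = coarse$gamma_grid)
  attr(sr, "results") <- attr(sr2, "results") <- NULL
  expect_identical(sr, sr2)
})

test_that("the selected best model recovers the planted informative features", {
  # 5 informative + 95 noise descriptors, delta = 3, 150/75 class imbalance:
  # the winning model should contain most of the true signal columns
  hits <- integer(10)
  for (s in 1:10) {
    ds <- make_descriptor_dataset(synthetic_spec(n_pos = 150, n_neg = 75,
                                                 delta = 3, seed = 100 + s))
    pr <- run_protocol(ds$matrix, ds$labels, n_runs = 5, seed = s)
    best <- select_best_model(pr)[[1]]
    hits[s] <- length(intersect(best$features, ds$informative))
  }
  expect_gte(sum(hits >= 4), 8)
})

test_that("external accuracy on real signal dominates label-permuted data", {
  pb <- small_problem(seed = 44, delta = 4)
  real <- run_protocol(pb$dm, pb$labels, pb$ext_dm, pb$ext_labels,
                       n_runs = 2, seed = 6, C_grid = coarse$C_grid,
                       gamma_grid = coarse$gamma_grid)
  set.seed(91)
  perm_lab <- setNames(sample(pb$labels), names(pb$labels))
  perm_ext <- setNames(sample(pb$ext_labels), names(pb$ext_labels))
  perm <- run_protocol(pb$dm, perm_lab, pb$ext_dm, perm_ext,
                       n_runs = 2, seed = 6, C_grid = coarse$C_grid,
                       gamma_grid = coarse$gamma_grid)
  expect_gte(real$means$acc[real$means$category == "external"],
             perm$means$acc[perm$means$category == "external"])
})
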