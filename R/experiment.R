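#' Random train/test split of compound ids
#'
#' `floor(fraction * n)` ids go to the training side (223 ids at 0.75 give
#' the 167/56 layout). Reproducible from the seed; stratified mode preserves
#' the class ratio to within one compound per class.
#'
#' @param ids Compound ids to partition.
#' @param fraction Training fraction in (0, 1).
#' @param seed RNG seed.
#' @param stratified Preserve class proportions (requires `labels`).
#' @param labels Named class labels, required when `stratified = TRUE`.
#' @return List with `train` and `test` id vectors.
#' @export
random_split <- function(ids, fraction, seed = 1, stratified = FALSE,
                         labels = NULL) {
  n <- length(ids)
  if (n < 2) stop("need at least 2 ids to split", call. = FALSE)
  stopifnot(fraction > 0, fraction < 1)
  n_train <- floor(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("fraction ", fraction, " yields an empty train or test side",
         call. = FALSE)
  if (stratified) {
    labels <- check_labels(labels, ids)
    train <- character(0)
    with_seed(seed, {
      for (cl in unique(labels)) {
        pool <- ids[labels == cl]
        k <- round(fraction * length(pool))
        k <- min(max(k, 1L), length(pool) - 1L)
        train <- c(train, pool[sample.int(length(pool), k)])
      }
    })
    # proportional rounding can drift from floor(fraction * n) by one or two;
    # keep the class balance and accept the small size difference
  } else {
    train <- with_seed(seed, ids[sample.int(n, n_train)])
  }
  list(train = train[order(match(train, ids))],
       test = setdiff(ids, train))
}

default_C_grid <- function() 2^seq(-5, 15, 2)
default_gamma_grid <- function() 2^seq(-15, 3, 2)

# One complete modelling run on a fixed split: scale on train, rank, prune,
# greedy-select, grid-search, final fit, evaluate everywhere.
single_run <- function(dmf, labels, ext_dm, ext_labels, split, kernel_kind,
                       run_seed, folds, r_threshold, greedy_cost, C_grid,
                       gamma_grid, degree, coef0, max_features,
                       greedy_patience) {
  train_ids <- split$train
  test_ids <- split$test
  y_train <- labels[train_ids]

  scaling <- fit_scaling(dmf, train_ids)
  x_all <- apply_scaling(dmf, scaling)
  x_train <- x_all[train_ids, , drop = FALSE]

  ranked <- rank_features(x_train, y_train)
  pruned <- prune_correlated(x_train, ranked, r_threshold)

  evaluator <- function(feats) {
    k <- if (kernel_kind == "linear") kernel_spec("linear")
         else kernel_spec(kernel_kind, gamma = 1 / length(feats),
                          degree = degree, coef0 = coef0)
    cv_accuracy(x_train[, feats, drop = FALSE], y_train, cost = greedy_cost,
                kernel = k, folds = folds, seed = run_seed)
  }
  trace <- greedy_forward_selection(pruned$retained, evaluator,
                                    baseline = majority_rate(y_train),
                                    max_features = max_features,
                                    patience = greedy_patience)
  feats <- trace$selected

  gs <- grid_search(x_train[, feats, drop = FALSE], y_train,
                    C_grid = C_grid, gamma_grid = gamma_grid,
                    folds = folds, seed = run_seed,
                    kernel_kind = kernel_kind, degree = degree, coef0 = coef0)
  kern <- if (kernel_kind == "linear") kernel_spec("linear")
          else kernel_spec(kernel_kind, gamma = gs$best_gamma,
                           degree = degree, coef0 = coef0)
  model <- svm_train(x_train[, feats, drop = FALSE], y_train,
                     cost = gs$best_cost, kernel = kern, scaling = scaling)

  report_on <- function(ids_or_x, truth) {
    pred <- predict(model, ids_or_x)
    evaluate_predictions(truth, pred)
  }
  reports <- list(
    training = report_on(x_train, y_train),
    test = report_on(x_all[test_ids, , drop = FALSE], labels[test_ids]))
  if (!is.null(ext_dm)) {
    x_ext <- apply_scaling(ext_dm[, colnames(dmf), drop = FALSE], scaling)
    reports$external <- report_on(x_ext, ext_labels)
  }
  structure(list(split = split, seed = run_seed, features = feats,
                 selection = trace, grid = gs,
                 cost = gs$best_cost, gamma = gs$best_gamma,
                 model = model, reports = reports),
            class = "run_record")
}

#' Multi-run random-split evaluation protocol
#'
#' The full modelling protocol: for each of `n_runs` random splits of the
#' modelling set, fit min-max scaling on the training rows, rank descriptors
#' by F-score, prune correlated descriptors, grow the feature set greedily
#' until cross-validated accuracy drops, grid-search C and gamma, refit on
#' the whole training set, and evaluate on the training, test and (once per
#' run, untouched otherwise) external sets. Mean metrics over runs are
#' reported per category. Descriptor elimination (sparsity/low-variation
#' filters) is applied to the modelling set once before splitting by default;
#' `filter_mode = "per_split"` refits the filters on each training split.
#'
#' @param dm Descriptor matrix of the modelling set.
#' @param labels Named class labels covering `dm`'s rows.
#' @param external_dm,external_labels Optional external validation set,
#'   disjoint from the modelling set; never used in model building.
#' @param fraction Training fraction; default 0.75.
#' @param kernel `"rbf"` (default), `"linear"` or `"polynomial"`.
#' @param n_runs Number of independent random splits; default 100.
#' @param seed Base seed; run r uses a seed derived from (seed, r).
#' @param folds CV folds for selection and grid search; default 5.
#' @param filter_mode `"pooled"` (filter once on the modelling set) or
#'   `"per_split"`.
#' @param zero_fraction,rel_sd Elimination thresholds (see
#'   [filter_descriptors()]).
#' @param r_threshold Correlation-pruning threshold; default 0.9.
#' @param greedy_cost C used during greedy forward selection; default 1.
#' @param max_features Cap on the number of descriptors the greedy walk may
#'   add; default 25. On strongly separable data cross-validated accuracy can
#'   plateau at its ceiling so that a strict decrease never occurs; the cap
#'   bounds model size (and runtime) in that regime.
#' @param greedy_patience Patience window for the greedy stop rule (see
#'   [greedy_forward_selection()]); default 0 (stop at first strict decrease).
#' @param C_grid,gamma_grid Grid-search ranges; defaults `2^seq(-5, 15, 2)`
#'   and `2^seq(-15, 3, 2)`.
#' @param degree,coef0 Polynomial kernel parameters.
#' @param stratified Stratify the random splits; default FALSE.
#' @return Object of class `protocol_result`: `runs` (list of `run_record`),
#'   `means` (data frame category x mean metrics), `failures`, `filter_report`,
#'   `settings`.
#' @export
run_protocol <- function(dm, labels, external_dm = NULL, external_labels = NULL,
                         fraction = 0.75, kernel = "rbf", n_runs = 100,
                         seed = 1, folds = 5,
                         filter_mode = c("pooled", "per_split"),
                         zero_fraction = 0.8, rel_sd = 0.03,
                         r_threshold = 0.9, greedy_cost = 1,
                         max_features = 25, greedy_patience = 0,
                         C_grid = default_C_grid(),
                         gamma_grid = default_gamma_grid(),
                         degree = 3L, coef0 = 0, stratified = FALSE) {
  filter_mode <- match.arg(filter_mode)
  check_matrix(dm)
  labels <- check_labels(labels, rownames(dm))
  if (!is.null(external_dm)) {
    check_matrix(external_dm)
    if (length(intersect(rownames(dm), rownames(external_dm))))
      stop("modelling and external sets overlap", call. = FALSE)
    external_labels <- check_labels(external_labels, rownames(external_dm))
  }

  flt_report <- NULL
  if (filter_mode == "pooled") {
    flt <- filter_descriptors(dm, zero_fraction, rel_sd)
    dmf_pooled <- flt$matrix
    flt_report <- flt$report
  }

  ids <- rownames(dm)
  runs <- vector("list", n_runs)
  failures <- character(0)
  for (r in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, r)
    res <- tryCatch({
      split <- random_split(ids, fraction, seed = run_seed,
                            stratified = stratified, labels = labels)
      dmf <- if (filter_mode == "pooled") dmf_pooled else {
        filter_descriptors(dm[split$train, , drop = FALSE],
                           zero_fraction, rel_sd)$matrix
        # per-split: thresholds fitted on train rows, then applied to all rows
      }
      if (filter_mode == "per_split")
        dmf <- dm[, colnames(dmf), drop = FALSE]
      single_run(dmf, labels, external_dm, external_labels, split, kernel,
                 run_seed, folds, r_threshold, greedy_cost, C_grid,
                 gamma_grid, degree, coef0, max_features, greedy_patience)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d: %s", r, conditionMessage(res)))
      if (length(failures) > max(1, 0.1 * n_runs))
        stop("more than 10% of runs failed; first failures:\n",
             paste(utils::head(failures, 3), collapse = "\n"), call. = FALSE)
      runs[r] <- list(NULL)
    } else {
      res$run <- r
      runs[[r]] <- res
    }
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("every run failed", call. = FALSE)
  structure(list(runs = runs[ok], means = mean_reports(runs[ok]),
                 failures = failures, filter_report = flt_report,
                 settings = list(fraction = fraction, kernel = kernel,
                                 n_runs = n_runs, seed = seed, folds = folds,
                                 filter_mode = filter_mode,
                                 C_grid = C_grid, gamma_grid = gamma_grid,
                                 r_threshold = r_threshold,
                                 stratified = stratified)),
            class = "protocol_result")
}

# Mean ACC/SE/SP/MCC per category over run records (NA metrics dropped).
mean_reports <- function(runs) {
  cats <- names(runs[[1]]$reports)
  do.call(rbind, lapply(cats, function(cat) {
    m <- do.call(rbind, lapply(runs, function(r) {
      rep <- r$reports[[cat]]
      c(acc = rep$acc, se = rep$se, sp = rep$sp, mcc = rep$mcc)
    }))
    data.frame(category = cat, t(colMeans(m, na.rm = TRUE)), n_runs = nrow(m))
  }))
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s kernel, %d runs (%d failed), fraction %.2f\n",
              x$settings$kernel, length(x$runs), length(x$failures),
              x$settings$fraction))
  df <- x$means
  df[c("acc", "se", "sp")] <- round(df[c("acc", "se", "sp")], 1)
  df$mcc <- round(df$mcc, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare kernel functions under the multi-run protocol
#'
#' Runs [run_protocol()] once per kernel with the same base seed (hence the
#' same random splits) and stacks the mean reports.
#'
#' @inheritParams run_protocol
#' @param kernels Kernels to compare.
#' @return Data frame: kernel, category, mean ACC/SE/SP/MCC, with attribute
#'   `results` holding the per-kernel `protocol_result`s.
#' @export
compare_kernels <- function(dm, labels, external_dm = NULL,
                            external_labels = NULL, fraction = 0.75,
                            kernels = c("linear", "polynomial", "rbf"),
                            n_runs = 100, seed = 1, ...) {
  results <- lapply(kernels, function(k)
    run_protocol(dm, labels, external_dm, external_labels,
                 fraction = fraction, kernel = k, n_runs = n_runs,
                 seed = seed, ...))
  names(results) <- kernels
  tab <- do.call(rbind, lapply(kernels, function(k)
    cbind(kernel = k, results[[k]]$means)))
  attr(tab, "results") <- results
  tab
}

#' Sweep training/test ratios under the multi-run protocol
#'
#' @inheritParams run_protocol
#' @param fractions Training fractions to sweep.
#' @return Data frame: fraction, category, mean metrics, with attribute
#'   `results`.
#' @export
sweep_ratios <- function(dm, labels, external_dm = NULL,
                         external_labels = NULL,
                         fractions = c(0.5, 0.6, 0.7, 0.75, 0.8, 0.85),
                         kernel = "rbf", n_runs = 100, seed = 1, ...) {
  results <- lapply(fractions, function(f)
    run_protocol(dm, labels, external_dm, external_labels, fraction = f,
                 kernel = kernel, n_runs = n_runs, seed = seed, ...))
  names(results) <- as.character(fractions)
  tab <- do.call(rbind, lapply(seq_along(fractions), function(i)
    cbind(fraction = fractions[i], results[[i]]$means)))
  attr(tab, "results") <- results
  tab
}

#' Select the best model from a set of runs
#'
#' Overfitting-aware selection rule: candidates are ranked by the absolute
#' difference between training and test accuracy (ascending), then by the
#' number of selected descriptors (ascending), then by run index. External
#' performance is never consulted.
#'
#' @param runs A `protocol_result` or a list of `run_record`s.
#' @return The list of runs in rank order (best first), with attribute
#'   `ranking`: a data frame (run, gap, n_features, train/test/external ACC).
#' @export
select_best_model <- function(runs) {
  if (inherits(runs, "protocol_result")) runs <- runs$runs
  stopifnot(length(runs) >= 1)
  ranking <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    data.frame(run = r$run %||% i,
               gap = abs(r$reports$training$acc - r$reports$test$acc),
               n_features = length(r$features),
               acc_train = r$reports$training$acc,
               acc_test = r$reports$test$acc,
               acc_external = if (!is.null(r$reports$external))
                 r$reports$external$acc else NA_real_)
  }))
  ord <- order(ranking$gap, ranking$n_features, ranking$run)
  structure(runs[ord], ranking = ranking[ord, , drop = FALSE])
}

#' Pairwise classification-overlap matrix across models
#'
#' Each model predicts the same compound set (raw descriptor values; each
#' model applies its own stored scaling) and every pair's agreement
#' percentage is tabulated.
#'
#' @param models List of at least two `bcrp_svm` models that store scaling
#'   parameters, e.g. from the runs of a `protocol_result`.
#' @param dm Raw (unscaled) descriptor matrix of the compounds to compare on.
#' @return Symmetric percentage matrix (diagonal 100) with attribute
#'   `summary` = min/mean/max of the off-diagonal entries.
#' @export
overlap_matrix <- function(models, dm) {
  if (length(models) < 2)
    stop("overlap analysis needs at least 2 models", call. = FALSE)
  check_matrix(dm)
  preds <- lapply(models, function(m) predict(m, dm, scaled = FALSE))
  k <- length(models)
  ids <- names(models) %||% paste0("model", seq_len(k))
  om <- matrix(100, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      om[i, j] <- om[j, i] <- classification_overlap(preds[[i]], preds[[j]])
    }
  }
  off <- om[upper.tri(om)]
  structure(om, summary = c(min = min(off), mean = mean(off), max = max(off)))
}

#' Predict the substrate class of query compounds
#'
#' End-to-end single-compound prediction: compute the model's descriptors
#' from the structure, apply the stored scaling, and classify. Works for
#' models whose features are all natively computable (see
#' [native_descriptors()]); models using ingested Dragon descriptors need a
#' descriptor table instead.
#'
#' @param model A `bcrp_svm` with stored scaling, or a path to a model file
#'   written by [write_model()].
#' @param structures A [molecule()], a list of molecules, or a character
#'   vector of SMILES strings (SMILES are 2D-only and are refused by models
#'   that use 3D descriptors).
#' @return Data frame: name, predicted label, decision value, and the
#'   descriptor values used.
#' @export
predict_compound <- function(model, structures) {
  if (is.character(model) && length(model) == 1 && file.exists(model))
    model <- read_model(model)
  stopifnot(inherits(model, "bcrp_svm"))
  if (is.null(model$scaling))
    stop("model carries no scaling parameters; cannot take raw structures",
         call. = FALSE)
  unknown <- setdiff(model$scaling$columns, native_descriptors())
  if (length(unknown))
    stop("model uses ingested descriptor(s) ", paste(unknown, collapse = ", "),
         "; supply a descriptor table via load_descriptor_table() instead",
         call. = FALSE)
  if (is.character(structures))
    structures <- lapply(structures, smiles_to_molecule)
  if (inherits(structures, "molecule")) structures <- list(structures)
  nms <- vapply(seq_along(structures), function(i) {
    nm <- structures[[i]]$name
    if (nzchar(nm)) nm else paste0("query", i)
  }, character(1))
  reg <- native_descriptor_list()
  vals <- do.call(rbind, lapply(structures, function(m)
    vapply(model$scaling$columns, function(d) reg[[d]](m), numeric(1))))
  rownames(vals) <- make.unique(nms)
  pred <- predict(model, vals, scaled = FALSE)
  data.frame(name = nms, label = as.character(pred),
             decision = unname(attr(pred, "decision")),
             vals, check.names = FALSE, row.names = NULL)
}
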