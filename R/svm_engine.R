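#' Kernel specification
#'
#' @param kind `"rbf"`, `"linear"` or `"polynomial"`.
#' @param gamma Kernel width parameter (> 0), used by the RBF and polynomial
#'   kernels. The RBF kernel is \eqn{K(x_i, x_j) = \exp(-\gamma \|x_i -
#'   x_j\|^2)}.
#' @param degree Polynomial degree (>= 1).
#' @param coef0 Polynomial offset.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial"),
                        gamma = NULL, degree = 3L, coef0 = 0) {
  kind <- match.arg(kind)
  if (kind != "linear") {
    if (is.null(gamma) || gamma <= 0)
      stop("gamma must be a positive real for the ", kind, " kernel",
           call. = FALSE)
  }
  degree <- as.integer(degree)
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  structure(list(kind = kind, gamma = gamma, degree = degree, coef0 = coef0),
            class = "kernel_spec")
}

#' Evaluate a kernel on two feature vectors
#'
#' @param k A [kernel_spec()].
#' @param x,y Numeric vectors of equal length.
#' @return Kernel value: dot product (linear),
#'   `(gamma * <x,y> + coef0)^degree` (polynomial), or
#'   `exp(-gamma * ||x - y||^2)` (RBF, always in (0, 1]).
#' @examples
#' kernel_value(kernel_spec("rbf", gamma = 1), c(0, 0), c(1, 0))  # exp(-1)
#' @export
kernel_value <- function(k, x, y) {
  stopifnot(inherits(k, "kernel_spec"))
  if (length(x) != length(y))
    stop("x and y must have the same dimension", call. = FALSE)
  switch(k$kind,
         linear = sum(x * y),
         polynomial = (k$gamma * sum(x * y) + k$coef0)^k$degree,
         rbf = exp(-k$gamma * sum((x - y)^2)))
}

# Kernel matrix between the rows of A (m x d) and B (s x d).
kernel_matrix <- function(k, A, B) {
  switch(k$kind,
         linear = A %*% t(B),
         polynomial = (k$gamma * (A %*% t(B)) + k$coef0)^k$degree,
         rbf = {
           sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
           exp(-k$gamma * pmax(sq, 0))
         })
}

as_class_factor <- function(labels) {
  factor(labels, levels = c(LABEL_SUBSTRATE, LABEL_NONSUBSTRATE))
}

training_fingerprint <- function(x, labels) {
  sprintf("n=%d;d=%d;sum=%.10g;sumsq=%.10g;pos=%d",
          nrow(x), ncol(x), sum(x), sum(x^2),
          sum(labels == LABEL_SUBSTRATE))
}

#' Train a soft-margin kernel SVM
#'
#' Fits a C-classification SVM (libsvm via e1071) on an already-scaled
#' feature matrix. The fitted state is stored as support vectors, dual
#' coefficients and bias, so the decision function
#' \eqn{f(x) = \sum_i \alpha_i y_i K(s_i, x) + b} can be evaluated (and
#' serialized) independently of the solver. Training is deterministic: the
#' same data and configuration always give the same decision values.
#'
#' @param x Numeric feature matrix (rows = compounds, already scaled).
#' @param labels Class labels (named by id or row-aligned), both classes
#'   present.
#' @param cost Soft-margin penalty C > 0.
#' @param kernel A [kernel_spec()]; default RBF with `gamma = 1/ncol(x)`.
#' @param class_weights Optional named positive weights per class.
#' @param scaling Optional `scaling_params` to store with the model so raw
#'   descriptor values can be fed to [predict.bcrp_svm()].
#' @return Object of class `bcrp_svm`: features, kernel config, support
#'   vectors, coefficients, bias, label orientation, training fingerprint.
#' @export
svm_train <- function(x, labels, cost = 1, kernel = NULL,
                      class_weights = NULL, scaling = NULL) {
  check_matrix(x, "feature matrix")
  labels <- check_labels(labels, rownames(x))
  if (length(unique(labels)) < 2)
    stop("training data contains a single class", call. = FALSE)
  if (cost <= 0) stop("cost must be > 0", call. = FALSE)
  if (is.null(kernel)) kernel <- kernel_spec("rbf", gamma = 1 / ncol(x))
  y <- as_class_factor(labels)
  ek <- switch(kernel$kind, rbf = "radial", linear = "linear",
               polynomial = "polynomial")
  fit <- e1071::svm(x = x, y = y, scale = FALSE, type = "C-classification",
                    kernel = ek, cost = cost,
                    gamma = kernel$gamma %||% 1,
                    degree = kernel$degree, coef0 = kernel$coef0,
                    class.weights = class_weights)
  # Orientation of libsvm's decision values: positive side = first class in
  # the "A/B" column name of the decision-value matrix.
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  sides <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]]
  structure(list(
    features = colnames(x),
    kernel = kernel,
    cost = cost,
    SV = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    positive_side = sides[1], negative_side = sides[2],
    scaling = scaling,
    fingerprint = training_fingerprint(x, labels),
    version = "bcrpsvm-model-1"),
    class = "bcrp_svm")
}

#' Decision values of a trained SVM
#'
#' Evaluates \eqn{f(x) = \sum_i \alpha_i y_i K(s_i, x) + b} directly from the
#' stored support vectors.
#'
#' @param model A `bcrp_svm`.
#' @param x Scaled feature matrix restricted (or restrictable) to the model's
#'   features.
#' @return Numeric decision values, named by row.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "bcrp_svm"))
  missing <- setdiff(model$features, colnames(x))
  if (length(missing))
    stop("matrix lacks model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- x[, model$features, drop = FALSE]
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  K <- kernel_matrix(model$kernel, as.matrix(x), model$SV)
  stats::setNames(drop(K %*% model$coefs) - model$rho, rownames(x))
}

#' Predict substrate class
#'
#' A decision value on the positive side maps to that side's class; exactly
#' zero maps to `"substrate"` (documented tie rule, set `tie` to change it).
#'
#' @param object A `bcrp_svm` model.
#' @param newdata Feature matrix. If the model stores scaling parameters and
#'   `scaled = FALSE`, raw descriptor values are scaled first.
#' @param scaled Whether `newdata` is already in the model's scaled space.
#' @param tie Class assigned to a decision value of exactly 0.
#' @param ... Unused.
#' @return Named character vector of labels with attribute `decision`.
#' @export
predict.bcrp_svm <- function(object, newdata, scaled = TRUE,
                             tie = LABEL_SUBSTRATE, ...) {
  if (!scaled) {
    if (is.null(object$scaling))
      stop("model carries no scaling parameters; pass scaled data", call. = FALSE)
    newdata <- apply_scaling(
      newdata[, object$scaling$columns, drop = FALSE], object$scaling)
  }
  dv <- decision_values(object, newdata)
  lab <- ifelse(dv > 0, object$positive_side,
                ifelse(dv < 0, object$negative_side, tie))
  structure(stats::setNames(lab, names(dv)), decision = dv)
}

#' @export
print.bcrp_svm <- function(x, ...) {
  cat(sprintf("<bcrp_svm> %s kernel, C=%g%s, %d support vectors, features: %s\n",
              x$kernel$kind, x$cost,
              if (!is.null(x$kernel$gamma)) sprintf(", gamma=%g", x$kernel$gamma) else "",
              nrow(x$SV), paste(x$features, collapse = ", ")))
  invisible(x)
}

# Deterministic stratified fold assignment: within each class, ids are
# shuffled under the seed and dealt round-robin, so every fold's training
# part keeps both classes whenever each class has >= 2 members.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Stratified k-fold cross-validated accuracy for one configuration.
cv_accuracy <- function(x, labels, cost, kernel, folds = 5, seed = 1,
                        fold_id = NULL) {
  if (is.null(fold_id)) fold_id <- stratified_folds(labels, folds, seed)
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    if (length(unique(labels[tr])) < 2) next
    m <- svm_train(x[tr, , drop = FALSE], labels[tr], cost = cost,
                   kernel = kernel)
    p <- predict(m, x[!tr, , drop = FALSE])
    correct <- correct + sum(p == labels[!tr])
  }
  correct / length(labels)
}

#' Exponential grid search for C and gamma
#'
#' Exhaustively evaluates every (C, gamma) pair on exponentially growing
#' sequences by stratified k-fold cross-validated accuracy on the training
#' set, and returns the best pair. Ties prefer the smaller C, then the
#' smaller gamma (the simplest model). For the linear kernel the gamma grid
#' collapses to a single placeholder.
#'
#' @param x Scaled feature matrix.
#' @param labels Class labels.
#' @param C_grid Cost values; default `2^seq(-5, 15, 2)`.
#' @param gamma_grid Gamma values; default `2^seq(-15, 3, 2)`.
#' @param folds Number of CV folds (>= 2); default 5.
#' @param seed Seed for the fold assignment; the search is fully reproducible
#'   given the seed.
#' @param kernel_kind `"rbf"` (default), `"linear"` or `"polynomial"`.
#' @param degree,coef0 Polynomial kernel parameters.
#' @return Object of class `grid_search_result`: `grid` (data frame cost,
#'   gamma, accuracy), `best_cost`, `best_gamma`, `best_accuracy`, `folds`,
#'   `seed`.
#' @export
grid_search <- function(x, labels, C_grid = 2^seq(-5, 15, 2),
                        gamma_grid = 2^seq(-15, 3, 2), folds = 5, seed = 1,
                        kernel_kind = "rbf", degree = 3L, coef0 = 0) {
  check_matrix(x, "feature matrix")
  labels <- check_labels(labels, rownames(x))
  stopifnot(folds >= 2, length(C_grid) >= 1)
  if (kernel_kind == "linear") gamma_grid <- NA_real_
  stopifnot(length(gamma_grid) >= 1)
  fold_id <- stratified_folds(labels, folds, seed)
  grid <- expand.grid(cost = C_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    k <- if (kernel_kind == "linear") kernel_spec("linear")
         else kernel_spec(kernel_kind, gamma = grid$gamma[i],
                          degree = degree, coef0 = coef0)
    cv_accuracy(x, labels, cost = grid$cost[i], kernel = k,
                fold_id = fold_id)
  }, numeric(1))
  ord <- order(-grid$accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1], ]
  structure(list(grid = grid, best_cost = best$cost, best_gamma = best$gamma,
                 best_accuracy = best$accuracy, folds = folds, seed = seed,
                 kernel_kind = kernel_kind),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search> %s kernel, %d combinations, best: C=%g, gamma=%s (CV accuracy %.1f%%)\n",
              x$kernel_kind, nrow(x$grid), x$best_cost, format(x$best_gamma),
              100 * x$best_accuracy))
  invisible(x)
}

#' Serialize a trained model to plain text (JSON)
#'
#' Writes every component needed to reproduce predictions: feature names,
#' scaling parameters, kernel configuration, support vectors, coefficients,
#' bias, label orientation and the training-set fingerprint.
#'
#' @param model A `bcrp_svm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bcrp_svm"))
  obj <- model
  class(obj) <- NULL
  if (!is.null(obj$scaling)) {
    obj$scaling <- list(center = as.list(obj$scaling$center),
                        halfwidth = as.list(obj$scaling$halfwidth),
                        columns = obj$scaling$columns,
                        fitted_on = obj$scaling$fitted_on)
  }
  obj$kernel <- unclass(obj$kernel)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_model()].
#' @return A `bcrp_svm` whose predictions are identical to the original's.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "bcrpsvm-model-1"))
    stop("unrecognized model file version: ", obj$version %||% "<missing>",
         call. = FALSE)
  obj$SV <- as.matrix(obj$SV)
  obj$kernel <- structure(
    list(kind = obj$kernel$kind, gamma = obj$kernel$gamma,
         degree = as.integer(obj$kernel$degree), coef0 = obj$kernel$coef0),
    class = "kernel_spec")
  if (!is.null(obj$scaling)) {
    obj$scaling <- structure(
      list(center = unlist(obj$scaling$center),
           halfwidth = unlist(obj$scaling$halfwidth),
           columns = obj$scaling$columns, fitted_on = obj$scaling$fitted_on),
      class = "scaling_params")
  }
  structure(obj, class = "bcrp_svm")
}
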