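#' Classifier specification
#'
#' Defaults where the method literature gives no single standard: Gaussian
#' Naive Bayes; KNN with `k = 5` and Euclidean distance on standardised
#' features; SVM with an RBF kernel and cost 1 on standardised features;
#' 10 stratified folds.
#'
#' @param method `"naive_bayes"`, `"knn"` or `"svm"`.
#' @param folds number of cross-validation folds (`>= 2`).
#' @param k neighbours for KNN (`>= 1`).
#' @param kernel,cost SVM kernel and cost.
#' @param seed seed controlling the fold assignment.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("naive_bayes", "knn", "svm"),
                            folds = 10, k = 5, kernel = "radial", cost = 1,
                            seed = 1) {
  method <- match.arg(method)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  structure(list(method = method, folds = folds, k = k, kernel = kernel,
                 cost = cost, seed = seed), class = "classifier_spec")
}

# stratified fold assignment: within each class, shuffled indices dealt
# round-robin into folds
stratified_folds <- function(labels, folds, seed) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated classification accuracy of the TDCH variables
#'
#' Stratified k-fold cross-validation of group membership from the feature
#' columns. Features are standardised using training-fold statistics for the
#' KNN and SVM methods. Reports the mean held-out accuracy and per-fold
#' detail.
#'
#' @param cohort data frame with a `group` column and the feature columns.
#' @param spec a [classifier_spec()].
#' @param features feature columns (default V1..V7).
#' @return a `cv_result`: one-row tibble (`method`, `accuracy`, `folds`,
#'   `seed`, `n`) with per-fold accuracies as attribute `per_fold`.
#' @export
cv_accuracy <- function(cohort, spec = classifier_spec(),
                        features = paste0("V", 1:7)) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!"group" %in% names(cohort)) stop("cohort needs a 'group' column", call. = FALSE)
  y <- factor(cohort$group)
  if (any(table(y) < spec$folds))
    stop("every class needs at least as many members as folds", call. = FALSE)
  X <- as.matrix(cohort[, features])
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  fold <- stratified_folds(as.character(y), spec$folds, spec$seed)
  acc <- vapply(seq_len(spec$folds), function(f) {
    tr <- fold != f; te <- fold == f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Str <- scale(Xtr, mu, sdv); Ste <- scale(Xte, mu, sdv)
    pred <- switch(spec$method,
      naive_bayes = {
        fit <- e1071::naiveBayes(Xtr, y[tr])
        stats::predict(fit, Xte)
      },
      knn = class::knn(Str, Ste, y[tr], k = spec$k),
      svm = {
        fit <- e1071::svm(Str, y[tr], kernel = spec$kernel, cost = spec$cost,
                          scale = FALSE)
        stats::predict(fit, Ste)
      })
    mean(pred == y[te])
  }, numeric(1))
  out <- tibble::tibble(method = spec$method, accuracy = mean(acc),
                        folds = spec$folds, seed = spec$seed, n = nrow(cohort))
  structure(out, per_fold = acc, class = c("cv_result", class(out)))
}

#' Run the full classifier battery
#'
#' Naive Bayes, KNN and SVM accuracies on the same stratified folds.
#'
#' @param cohort data frame with a `group` column and the feature columns.
#' @param folds,seed cross-validation settings shared across methods.
#' @param features feature columns.
#' @return a tibble with one row per method.
#' @export
classify_battery <- function(cohort, folds = 10, seed = 1,
                             features = paste0("V", 1:7)) {
  purrr::map_dfr(c("naive_bayes", "knn", "svm"), function(m) {
    cv_accuracy(cohort, classifier_spec(method = m, folds = folds, seed = seed),
                features = features)
  })
}
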