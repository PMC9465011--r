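#' Fit one of the four bruise classifiers
#'
#' Wraps the four pixel classifiers used throughout the workflow: linear
#' and quadratic discriminant analysis, a linear-kernel support vector
#' machine (slack penalty C = 1) and an RBF-kernel SVM (C = 1, kernel
#' width from the median heuristic on the training data). Features are
#' standardized with training-set statistics before either SVM;
#' discriminant analyses, being affine-equivariant, run on the raw
#' reflectance. If a QDA class covariance is singular, a small ridge is
#' added to the class covariances via jittering, once.
#'
#' @param x Training feature matrix (n x p).
#' @param y Factor of class labels.
#' @param method One of `"lda"`, `"qda"`, `"svm"`, `"svm_rbf"`.
#' @param cost SVM slack penalty.
#' @return An object of class `bruise_classifier`.
#' @export
fit_classifier <- function(x, y, method = c("lda", "qda", "svm", "svm_rbf"),
                           cost = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training data must contain both classes")
  ctr <- NULL; scl <- NULL
  fit <- switch(method,
    lda = MASS::lda(x, grouping = y),
    qda = tryCatch(MASS::qda(x, grouping = y), error = function(e) {
      MASS::qda(x + matrix(stats::rnorm(length(x), 0,
                                        1e-6 * max(stats::sd(x), 1e-12)),
                           nrow(x)), grouping = y)
    }),
    svm = {
      ctr <- colMeans(x); scl <- pmax(apply(x, 2, stats::sd), 1e-12)
      xs <- scale(x, ctr, scl)
      e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
    },
    svm_rbf = {
      ctr <- colMeans(x); scl <- pmax(apply(x, 2, stats::sd), 1e-12)
      xs <- scale(x, ctr, scl)
      gamma <- 1 / (2 * median_heuristic_sq(xs))
      e1071::svm(xs, y, kernel = "radial", cost = cost, gamma = gamma,
                 scale = FALSE)
    })
  structure(list(method = method, fit = fit, center = ctr, scale = scl,
                 p = ncol(x), levels = levels(y)),
            class = "bruise_classifier")
}

# median of pairwise squared distances (subsampled for large n)
median_heuristic_sq <- function(x, max_n = 400) {
  n <- nrow(x)
  if (n > max_n) x <- x[seq(1, n, length.out = max_n), , drop = FALSE]
  d2 <- as.vector(stats::dist(x))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Predict class labels with a fitted bruise classifier
#'
#' @param object A `bruise_classifier`.
#' @param newdata Feature matrix with the same columns as at fit time.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.bruise_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature count does not match the fitted model")
  if (object$method %in% c("svm", "svm_rbf")) {
    xs <- scale(newdata, object$center, object$scale)
    stats::predict(object$fit, xs)
  } else {
    stats::predict(object$fit, newdata)$class
  }
}

#' Stratified k-fold cross-validated accuracy
#'
#' Folds are stratified by class; the fold assignment can be supplied so
#' that competing feature subsets are compared on identical folds.
#'
#' @param x Feature matrix.
#' @param y Factor labels.
#' @param method Classifier id, see [fit_classifier()].
#' @param folds Number of folds.
#' @param fold_id Optional integer fold assignment of length `nrow(x)`.
#' @param seed Seed used when `fold_id` is generated here.
#' @return Mean accuracy over folds.
#' @export
cv_accuracy <- function(x, y, method, folds = 5, fold_id = NULL, seed = 1) {
  x <- as.matrix(x); y <- as.factor(y)
  if (is.null(fold_id)) fold_id <- make_folds(y, folds, seed)
  acc <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    if (nlevels(droplevels(y[tr])) < 2 || nlevels(droplevels(y[!tr])) < 1)
      stop("a fold lost a class; stratification failed")
    m <- fit_classifier(x[tr, , drop = FALSE], y[tr], method)
    mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc)
}

# stratified fold assignment
make_folds <- function(y, folds = 5, seed = 1) {
  set.seed(as.integer(seed))
  id <- integer(length(y))
  for (lv in levels(y)) {
    i <- which(y == lv)
    if (length(i) < folds)
      stop("class '", lv, "' has fewer members than folds")
    id[i] <- sample(rep(seq_len(folds), length.out = length(i)))
  }
  id
}
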