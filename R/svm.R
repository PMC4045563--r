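#' Inhomogeneous polynomial kernel
#'
#' `K(x, y) = (x . y + 1)^degree`. As a global kernel it lets training
#' points far from a test point still contribute to the decision value.
#'
#' @param x,y numeric vectors of equal length.
#' @param degree integer polynomial order, >= 1.
#' @return a single number.
#' @examples
#' polynomial_kernel(c(1, 1), c(1, 1), degree = 2) # (2 + 1)^2 = 9
#' @export
polynomial_kernel <- function(x, y, degree = 4L) {
  if (length(x) != length(y)) {
    stop("kernel arguments must have equal dimension", call. = FALSE)
  }
  if (degree < 1 || degree != as.integer(degree)) {
    stop("degree must be a positive integer", call. = FALSE)
  }
  (sum(x * y) + 1)^degree
}

#' Classifier configuration
#'
#' @param degree polynomial kernel order (default 4; orders 2-4 are the
#'   usual operating range, 4 performing best on fractal MRI features).
#' @param C soft-margin penalty > 0 controlling the tradeoff between margin
#'   width and training violations (default 1).
#' @param standardize z-score each feature using training-set mean and
#'   standard deviation before the kernel (default TRUE; polynomial kernels
#'   are scale-sensitive across features of different magnitude).
#' @return a list of class `"svm_config"`.
#' @export
svm_config <- function(degree = 4L, C = 1.0, standardize = TRUE) {
  degree <- as.integer(degree)
  if (degree < 1L || degree > 10L) {
    stop("degree must be an integer in 1..10", call. = FALSE)
  }
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("C must be a positive number", call. = FALSE)
  }
  structure(list(degree = degree, C = C,
                 standardize = isTRUE(standardize)),
            class = "svm_config")
}

#' Train a soft-margin polynomial-kernel SVM
#'
#' Solves the soft-margin dual (libsvm, via \pkg{e1071}) with the
#' inhomogeneous polynomial kernel, then stores the support vectors,
#' multipliers `alpha_i`, labels and bias in a form that makes the decision
#' function
#' \deqn{g(x) = sign\left(\sum_i y_i \alpha_i K(x, x_i) + b\right)}
#' directly computable by [predict.msa_svm()]. When `standardize` is on,
#' per-feature location and scale are estimated from the training data only
#' and stored in the model.
#'
#' The returned model satisfies the dual constraints `sum(alpha_i y_i) = 0`
#' and `0 <= alpha_i <= C`.
#'
#' @param features numeric matrix or data frame, one row per sample.
#' @param labels vector of class labels in {+1, -1}.
#' @param config an [svm_config()].
#' @return an object of class `"msa_svm"`.
#' @export
svm_train <- function(features, labels, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.numeric(labels)
  if (nrow(x) != length(y)) {
    stop("features and labels differ in length", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("invalid input: non-finite feature values", call. = FALSE)
  }
  if (!all(y %in% c(-1, 1))) {
    stop("labels must be +1 or -1", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: both classes must be present",
         call. = FALSE)
  }

  if (config$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")

  fit <- e1071::svm(xs, factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "polynomial",
                    degree = config$degree, gamma = 1, coef0 = 1,
                    cost = config$C, scale = FALSE)

  coefs <- as.numeric(fit$coefs)   # alpha_i * y_i, sign per fit$labels[1]
  rho <- fit$rho
  # libsvm's decision value is positive for the class listed first in
  # fit$labels; flip so that positive always means the +1 class
  pos_first <- fit$levels[fit$labels[1]] == "1"
  if (!pos_first) {
    coefs <- -coefs
    rho <- -rho
  }

  structure(list(support_vectors = unname(as.matrix(fit$SV)),
                 alphas = abs(coefs),
                 support_labels = sign(coefs),
                 coefs = coefs,
                 bias = -rho,
                 center = center,
                 scale = scale,
                 config = config,
                 n_features = ncol(x)),
            class = "msa_svm")
}

#' @export
print.msa_svm <- function(x, ...) {
  cat(sprintf(
    "Polynomial-kernel SVM: degree %d, C = %g, %d support vectors, %d features\n",
    x$config$degree, x$config$C, length(x$alphas), x$n_features))
  invisible(x)
}

#' Decision values of a trained SVM
#'
#' Evaluates `sum_i y_i alpha_i K(x, x_i) + b` for each row of `newdata`,
#' after applying the standardization stored in the model.
#'
#' @param model an `"msa_svm"` from [svm_train()].
#' @param newdata numeric matrix/data frame of feature rows, or a single
#'   feature vector.
#' @return numeric vector of decision values.
#' @export
decision_values <- function(model, newdata) {
  stopifnot(inherits(model, "msa_svm"))
  x <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1)
       else as.matrix(newdata)
  if (ncol(x) != model$n_features) {
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(x), model$n_features), call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  gram <- (xs %*% t(model$support_vectors) + 1)^model$config$degree
  as.numeric(gram %*% model$coefs + model$bias)
}

#' Predict class labels with a trained SVM
#'
#' @param object an `"msa_svm"` model.
#' @param newdata feature matrix or single feature vector.
#' @param ... unused.
#' @return integer vector of labels in {+1, -1}. A decision value of exactly
#'   zero is mapped to -1 (the negative/normal class), a fixed deterministic
#'   convention.
#' @export
predict.msa_svm <- function(object, newdata, ...) {
  g <- decision_values(object, newdata)
  ifelse(g > 0, 1L, -1L)
}

#' Leave-one-out cross-validation of the SVM pipeline
#'
#' Each sample is predicted by a model trained on all remaining samples;
#' standardization parameters are recomputed inside every fold from its
#' training split only, so no information from the held-out sample leaks
#' into the model. Aggregates the held-out predictions into the correct
#' classification rate (CCR), sensitivity (correct-positive rate, +1 class)
#' and specificity (correct-negative rate, -1 class), together with the
#' sample standard deviation of the per-fold 0/1 correctness indicators
#' overall and within each class.
#'
#' @param features numeric matrix or data frame of feature rows.
#' @param labels vector in {+1, -1}; +1 is the positive (disease) class.
#' @param config an [svm_config()].
#' @param ids optional per-sample identifiers.
#' @return object of class `"loocv_report"`: list with `per_fold` (data frame
#'   `id`, `truth`, `predicted`, `correct`), `ccr`, `sensitivity`,
#'   `specificity`, `ccr_std`, `sens_std`, `spec_std`, `n`, and the config.
#' @export
evaluate_loocv <- function(features, labels, config = svm_config(),
                           ids = NULL) {
  x <- as.matrix(features)
  y <- as.numeric(labels)
  n <- nrow(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (length(y) != n || length(ids) != n) {
    stop("features, labels and ids differ in length", call. = FALSE)
  }
  if (sum(y == 1) < 2L || sum(y == -1) < 2L) {
    stop("insufficient data: each class needs >= 2 samples for LOOCV",
         call. = FALSE)
  }
  pred <- integer(n)
  for (i in seq_len(n)) {
    model <- svm_train(x[-i, , drop = FALSE], y[-i], config)
    pred[i] <- predict(model, x[i, ])
  }
  per_fold <- data.frame(id = ids, truth = as.integer(y),
                         predicted = pred,
                         correct = as.integer(pred == y),
                         stringsAsFactors = FALSE)
  metrics <- classification_metrics(per_fold$truth, per_fold$predicted)
  structure(c(list(per_fold = per_fold), metrics, list(config = config)),
            class = "loocv_report")
}

#' Classification metrics from truth/prediction vectors
#'
#' CCR = correct / total; sensitivity = correct positives / positives;
#' specificity = correct negatives / negatives. The `*_std` fields are the
#' sample standard deviations of the corresponding 0/1 correctness
#' indicators.
#'
#' @param truth,predicted vectors of labels in {+1, -1}.
#' @return list with `ccr`, `sensitivity`, `specificity`, `ccr_std`,
#'   `sens_std`, `spec_std` and `n`.
#' @export
classification_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  correct <- as.numeric(truth == predicted)
  pos <- truth == 1
  neg <- truth == -1
  list(ccr = mean(correct),
       sensitivity = if (any(pos)) mean(correct[pos]) else NA_real_,
       specificity = if (any(neg)) mean(correct[neg]) else NA_real_,
       ccr_std = stats::sd(correct),
       sens_std = if (sum(pos) > 1) stats::sd(correct[pos]) else NA_real_,
       spec_std = if (sum(neg) > 1) stats::sd(correct[neg]) else NA_real_,
       n = length(truth))
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (%d samples)\n", x$n))
  cat(sprintf("  CCR:         %.2f%% +/- %.4f\n", 100 * x$ccr, x$ccr_std))
  cat(sprintf("  Sensitivity: %.2f%% +/- %.4f\n",
              100 * x$sensitivity, x$sens_std))
  cat(sprintf("  Specificity: %.2f%% +/- %.4f\n",
              100 * x$specificity, x$spec_std))
  cat(sprintf("  Kernel degree %d, C = %g, standardize = %s\n",
              x$config$degree, x$config$C, x$config$standardize))
  invisible(x)
}
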