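# Three-class blood-pressure classification: class discretization, stratified
# splitting, a from-scratch L2-regularized softmax multinomial logistic
# regression trained by full-batch gradient descent, and confusion-matrix /
# ROC evaluation.

#' Discretize blood pressure into three classes
#'
#' SBP: class 0 below 120 mmHg, class 1 from 120 to 135 mmHg, class 2 above
#' 135 mmHg.  DBP: class 0 below 80 mmHg, class 1 from 80 to 85 mmHg, class 2
#' above 85 mmHg.  Boundary convention: values exactly on a bin edge (120,
#' 135, 80, 85) belong to the middle class.
#'
#' @param sbp systolic pressure(s) in mmHg (> 0).
#' @param dbp diastolic pressure(s) in mmHg (> 0).
#' @return for scalar input, integer vector `c(sbp_class, dbp_class)`; for
#'   vector input, a two-column matrix.
#' @export
#' @examples
#' discretize_bp(121, 79)  # c(1, 0)
discretize_bp <- function(sbp, dbp) {
  if (any(sbp <= 0) || any(dbp <= 0)) stop("blood pressure must be positive")
  sbp_class <- ifelse(sbp < 120, 0L, ifelse(sbp <= 135, 1L, 2L))
  dbp_class <- ifelse(dbp < 80, 0L, ifelse(dbp <= 85, 1L, 2L))
  if (length(sbp) == 1L && length(dbp) == 1L) {
    c(sbp_class = sbp_class, dbp_class = dbp_class)
  } else {
    cbind(sbp_class = sbp_class, dbp_class = dbp_class)
  }
}

#' Stratified random train/test split
#'
#' Samples `test_fraction` of each class (rounded so the overall test size is
#' `round(n * test_fraction)` as closely as stratification allows) into the
#' test set; reproducible by seed.
#'
#' @param x feature matrix (rows = samples).
#' @param y class labels (any discrete type).
#' @param test_fraction fraction in (0, 1); default 0.3.
#' @param seed integer RNG seed.
#' @return list with `train` and `test`, each a list of `x`, `y`, `idx`.
#' @export
train_test_split <- function(x, y, test_fraction = 0.3, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  y <- as.vector(y)
  classes <- sort(unique(y))
  if (any(table(y) < 2L)) {
    stop("every class needs at least 2 samples so both partitions contain it")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in classes) {
    idx <- which(y == cl)
    n_test <- round(length(idx) * test_fraction)
    n_test <- max(min(n_test, length(idx) - 1L), 1L)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  list(train = list(x = x[train_idx, , drop = FALSE], y = y[train_idx],
                    idx = train_idx),
       test = list(x = x[test_idx, , drop = FALSE], y = y[test_idx],
                   idx = test_idx))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit a softmax multinomial logistic regression
#'
#' Minimizes the L2-regularized multinomial cross-entropy (mean over samples;
#' intercepts unpenalized) by full-batch gradient descent from a zero
#' initialization, stopping when the loss decreases by less than `tol` or
#' after `max_iter` steps.  Features are standardized internally with
#' training-set means and SDs, which are stored in the model.
#'
#' @param x feature matrix (rows = samples), finite entries.
#' @param y class labels; coerced to factor, 3 classes expected.
#' @param lambda L2 penalty strength.
#' @param lr learning rate.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the loss decrease.
#' @return object of class `softmax_model`: `coef` (classes x features),
#'   `intercept` (classes), `center`/`scale` (standardization), `levels`,
#'   `loss_trace`, `converged`, hyperparameters.
#' @export
fit_multinomial_lr <- function(x, y, lambda = 1e-3, lr = 0.1,
                               max_iter = 5000L, tol = 1e-8) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  y <- factor(y)
  k <- nlevels(y)
  n <- nrow(x)
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")

  yi <- matrix(0, n, k)
  yi[cbind(seq_len(n), as.integer(y))] <- 1

  w <- matrix(0, k, ncol(x))
  b <- numeric(k)
  loss_trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    z <- xs %*% t(w) + matrix(b, n, k, byrow = TRUE)
    p <- softmax_rows(z)
    loss <- -mean(log(pmax(p[yi == 1], 1e-300))) +
      lambda / 2 * sum(w^2)
    loss_trace <- c(loss_trace, loss)
    g <- p - yi
    gw <- t(g) %*% xs / n + lambda * w
    gb <- colMeans(g)
    w <- w - lr * gw
    b <- b - lr * gb
    if (abs(prev - loss) < tol) { converged <- TRUE; break }
    prev <- loss
  }
  structure(list(coef = w, intercept = b, center = center, scale = scl,
                 levels = levels(y), loss_trace = loss_trace,
                 converged = converged,
                 hyper = list(lambda = lambda, lr = lr, max_iter = max_iter,
                              tol = tol)),
            class = "softmax_model")
}

#' @export
print.softmax_model <- function(x, ...) {
  cat(sprintf(
    "<softmax_model> %d classes x %d features, %d iterations (%sconverged)\n",
    length(x$levels), ncol(x$coef), length(x$loss_trace),
    if (x$converged) "" else "not "))
  invisible(x)
}

#' Softmax class probabilities
#'
#' @param m a `softmax_model`.
#' @param x feature matrix with the same columns the model was fitted on.
#' @return matrix of class probabilities (rows sum to 1), columns named by
#'   class level.
#' @export
predict_proba <- function(m, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(m$coef)) stop("feature dimension mismatch")
  xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  z <- xs %*% t(m$coef) + matrix(m$intercept, nrow(x), length(m$intercept),
                                 byrow = TRUE)
  p <- softmax_rows(z)
  colnames(p) <- m$levels
  p
}

#' One-vs-rest ROC curve by threshold sweep
#'
#' @param truth logical vector, `TRUE` for the positive class.
#' @param score numeric class probability/score.
#' @return data frame with `threshold`, `tpr`, `fpr`, sorted for trapezoid
#'   integration.
#' @export
roc_curve <- function(truth, score) {
  stopifnot(length(truth) == length(score))
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  pos <- sum(truth); neg <- sum(!truth)
  tpr <- vapply(thr, function(th) sum(score >= th & truth) / max(pos, 1),
                numeric(1))
  fpr <- vapply(thr, function(th) sum(score >= th & !truth) / max(neg, 1),
                numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  sum(diff(roc$fpr[o]) * (head(roc$tpr[o], -1) + tail(roc$tpr[o], -1)) / 2)
}

#' Evaluate three-class predictions
#'
#' Hard labels by the argmax rule; 3x3 confusion matrix (rows = truth,
#' columns = prediction), overall accuracy, and per-class one-vs-rest ROC
#' with trapezoid AUC.
#'
#' @param y_true true labels.
#' @param proba probability matrix from [predict_proba()].
#' @return object of class `eval_report`: `confusion`, `accuracy`, `roc`
#'   (list per class), `auc` (named numeric), `n`.
#' @export
evaluate_classifier <- function(y_true, proba) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != nrow(proba)) stop("length mismatch")
  lev <- colnames(proba)
  y_true <- factor(y_true, levels = lev)
  pred <- factor(lev[max.col(proba, ties.method = "first")], levels = lev)
  confusion <- table(truth = y_true, predicted = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  rocs <- lapply(lev, function(cl) roc_curve(y_true == cl, proba[, cl]))
  names(rocs) <- lev
  auc <- vapply(rocs, trapezoid_auc, numeric(1))
  structure(list(confusion = confusion, accuracy = acc, roc = rocs,
                 auc = auc, n = length(y_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d accuracy=%.3f AUC: %s\n", x$n, x$accuracy,
              paste(sprintf("%s=%.3f", names(x$auc), x$auc),
                    collapse = " ")))
  print(x$confusion)
  invisible(x)
}

#' Train and evaluate the BP classifiers on a screened feature set
#'
#' Stratified 70/30 split, softmax multinomial fit and held-out evaluation
#' for one target (`"sbp"` or `"dbp"`).
#'
#' @param feats output of [dataset_features()].
#' @param target `"sbp"` or `"dbp"`.
#' @param test_fraction held-out fraction.
#' @param seed split seed.
#' @param ... hyperparameters forwarded to [fit_multinomial_lr()].
#' @return list with `model` (`softmax_model`) and `report` (`eval_report`).
#' @export
train_bp_classifier <- function(feats, target = c("sbp", "dbp"),
                                test_fraction = 0.3, seed = 1L, ...) {
  target <- match.arg(target)
  y <- feats$labels[[paste0(target, "_class")]]
  split <- train_test_split(feats$features, y, test_fraction, seed)
  model <- fit_multinomial_lr(split$train$x, split$train$y, ...)
  proba <- predict_proba(model, split$test$x)
  list(model = model,
       report = evaluate_classifier(split$test$y, proba),
       split = split)
}
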