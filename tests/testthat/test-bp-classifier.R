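test_that("blood-pressure discretization follows the class bins", {
  expect_equal(unname(discretize_bp(119.9, 70)["sbp_class"]), 0L)
  expect_equal(unname(discretize_bp(136, 70)["sbp_class"]), 2L)
  expect_equal(unname(discretize_bp(121, 79)), c(1L, 0L))
  # boundary convention: bin edges belong to the middle class
  expect_equal(unname(discretize_bp(120, 85)), c(1L, 1L))
  expect_equal(unname(discretize_bp(135, 80)), c(1L, 1L))
  m <- discretize_bp(c(110, 125, 150), c(75, 82, 95))
  expect_equal(unname(m[, "sbp_class"]), c(0L, 1L, 2L))
  expect_equal(unname(m[, "dbp_class"]), c(0L, 1L, 2L))
  expect_error(discretize_bp(-1, 80), "positive")
})

test_that("stratified split is exhaustive, disjoint and reproducible", {
  set.seed(1)
  x <- matrix(rnorm(200), ncol = 2)
  y <- rep(0:2, length.out = 100)
  sp <- train_test_split(x, y, 0.3, seed = 5)
  expect_length(sp$test$y, 30)
  expect_length(sp$train$y, 70)
  expect_length(intersect(sp$train$idx, sp$test$idx), 0)
  expect_setequal(c(sp$train$idx, sp$test$idx), 1:100)
  # class proportions within one sample of the stratified ideal
  tt <- table(factor(sp$test$y, 0:2))
  ideal <- table(factor(y, 0:2)) * 0.3
  expect_true(all(abs(tt - ideal) <= 1))
  sp2 <- train_test_split(x, y, 0.3, seed = 5)
  expect_identical(sp$test$idx, sp2$test$idx)
  expect_error(train_test_split(x, y, 0), "test_fraction")
  expect_error(train_test_split(x[1:4, ], c(0, 0, 0, 1)), "class")
})

test_that("softmax regression learns separable data and nulls correctly", {
  # uninformative features: fitted probabilities approach the class priors
  set.seed(2)
  xnull <- matrix(rnorm(300), ncol = 2)
  ynull <- rep(c(0, 0, 1, 2, 2, 2), length.out = 150)
  mnull <- fit_multinomial_lr(xnull, ynull)
  p <- colMeans(predict_proba(mnull, xnull))
  priors <- as.numeric(table(factor(ynull, 0:2)) / 150)
  expect_equal(unname(p), priors, tolerance = 0.05)

  # three separated clusters are fit to 100% training accuracy
  set.seed(3)
  centers <- rbind(c(-4, 0), c(4, 0), c(0, 6))
  xs <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(80, sd = 0.5), ncol = 2), 2, centers[k, ], "+")))
  ys <- rep(0:2, each = 40)
  msep <- fit_multinomial_lr(xs, ys)
  pred <- max.col(predict_proba(msep, xs)) - 1
  expect_equal(mean(pred == ys), 1)

  # training loss is non-increasing under the default learning rate
  expect_true(all(diff(msep$loss_trace) <= 1e-12))
  expect_error(fit_multinomial_lr(matrix(c(1, NA), 1), 0), "finite")
})

test_that("the fitted optimum has (numerically) vanishing gradient", {
  set.seed(4)
  x <- matrix(rnorm(240), ncol = 2)
  y <- rep(0:2, each = 40)
  lambda <- 1e-3
  m <- fit_multinomial_lr(x, y, lambda = lambda, max_iter = 20000,
                          tol = 1e-12)
  # finite-difference gradient of the regularized loss at the optimum
  xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  yi <- matrix(0, nrow(x), 3)
  yi[cbind(seq_len(nrow(x)), y + 1)] <- 1
  loss_at <- function(w, b) {
    z <- xs %*% t(w) + matrix(b, nrow(xs), 3, byrow = TRUE)
    pz <- exp(z - apply(z, 1, max))
    pz <- pz / rowSums(pz)
    -mean(log(pz[yi == 1])) + lambda / 2 * sum(w^2)
  }
  eps <- 1e-6
  g <- numeric(0)
  for (i in seq_along(m$coef)) {
    wp <- m$coef; wm <- m$coef
    wp[i] <- wp[i] + eps; wm[i] <- wm[i] - eps
    g <- c(g, (loss_at(wp, m$intercept) - loss_at(wm, m$intercept)) /
             (2 * eps))
  }
  expect_lt(sqrt(sum(g^2)), 1e-4)
})

test_that("softmax probabilities are normalized and shift-invariant", {
  m <- structure(list(coef = matrix(0, 3, 2), intercept = rep(0, 3),
                      center = c(0, 0), scale = c(1, 1),
                      levels = c("0", "1", "2")),
                 class = "softmax_model")
  x <- matrix(rnorm(20), ncol = 2)
  p0 <- predict_proba(m, x)
  expect_equal(unname(p0), matrix(1 / 3, 10, 3), tolerance = 1e-12)

  set.seed(6)
  m$coef <- matrix(rnorm(6), 3, 2)
  m$intercept <- rnorm(3)
  p1 <- predict_proba(m, x)
  expect_equal(rowSums(p1), rep(1, 10), tolerance = 1e-9)
  expect_true(all(p1 > 0 & p1 < 1))
  m2 <- m
  m2$intercept <- m$intercept + 5    # constant score shift
  expect_equal(predict_proba(m2, x), p1, tolerance = 1e-9)

  m3 <- m
  m3$intercept <- c(50, 0, 0)        # one dominating logit
  expect_gt(predict_proba(m3, x)[1, 1], 1 - 1e-9)
  expect_error(predict_proba(m, matrix(1, 2, 5)), "dimension")
})

test_that("evaluation reproduces hand-computed confusion matrices and ROC", {
  # perfect predictions
  y <- c(0, 0, 1, 1, 2, 2)
  p_perfect <- diag(3)[y + 1, ]
  colnames(p_perfect) <- c("0", "1", "2")
  ev <- evaluate_classifier(y, p_perfect)
  expect_equal(unname(diag(ev$confusion)), c(2, 2, 2))
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$auc), rep(1, 3))

  # hand-built 6-sample case: one 0 predicted as 1, one 2 predicted as 0
  p_hand <- rbind(c(0.8, 0.1, 0.1), c(0.2, 0.7, 0.1), c(0.1, 0.8, 0.1),
                  c(0.2, 0.1, 0.7), c(0.6, 0.2, 0.2), c(0.1, 0.2, 0.7))
  colnames(p_hand) <- c("0", "1", "2")
  y_hand <- c(0, 0, 1, 2, 2, 2)
  ev_hand <- evaluate_classifier(y_hand, p_hand)
  expect_equal(unname(as.vector(ev_hand$confusion)),
               c(1, 0, 1, 1, 1, 0, 0, 0, 2))
  expect_equal(ev_hand$accuracy, 4 / 6)

  # Monte-Carlo null: random scores give chance accuracy and AUC 0.5
  set.seed(8)
  n <- 3000
  y_mc <- sample(0:2, n, replace = TRUE)
  p_mc <- matrix(runif(3 * n), ncol = 3)
  p_mc <- p_mc / rowSums(p_mc)
  colnames(p_mc) <- c("0", "1", "2")
  ev_mc <- evaluate_classifier(y_mc, p_mc)
  expect_equal(ev_mc$accuracy, 1 / 3, tolerance = 0.09)
  expect_equal(unname(ev_mc$auc), rep(0.5, 3), tolerance = 0.06)
  expect_error(evaluate_classifier(integer(0), p_mc), "empty")
})

test_that("fit agrees with an independent optimizer and AUC with pROC", {
  skip_if_not_installed("nnet")
  skip_if_not_installed("pROC")
  set.seed(10)
  n <- 210
  y <- rep(0:2, each = n / 3)
  x <- cbind(rnorm(n, y), rnorm(n, 0.5 * y))   # overlapping classes
  m <- fit_multinomial_lr(x, y, lambda = 0, lr = 0.3, max_iter = 50000,
                          tol = 1e-13)
  p_ours <- predict_proba(m, x)
  ref <- nnet::multinom(y ~ x, trace = FALSE, maxit = 1000, reltol = 1e-14)
  p_ref <- stats::fitted(ref)
  expect_lt(mean(abs(p_ours - p_ref)), 1e-3)

  score <- p_ours[, "2"]
  roc_ref <- pROC::roc(response = as.integer(y == 2), predictor = score,
                       quiet = TRUE, direction = "<")
  expect_equal(trapezoid_auc_pkg <- scgtwin:::trapezoid_auc(
    roc_curve(y == 2, score)), as.numeric(pROC::auc(roc_ref)),
    tolerance = 1e-9)
})

test_that("planted BP mapping is recovered on a small screened dataset", {
  ds <- synthesize_bp_dataset(45, seed = 7)
  feats <- dataset_features(ds)
  expect_gte(nrow(feats$features), 40)
  for (tg in c("sbp", "dbp")) {
    fit <- train_bp_classifier(feats, tg, seed = 7)
    expect_gte(fit$report$accuracy, 0.85)
    expect_equal(sum(fit$report$confusion), fit$report$n)
  }
})
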