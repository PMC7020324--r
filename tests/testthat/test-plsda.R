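test_that("class encoding produces one-hot rows in level order", {
  y <- encode_classes(c("a", "b", "a"))
  expect_equal(unname(y), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_true(all(rowSums(y) == 1))
  y4 <- encode_classes(rep(mirfuse_species(), 2), levels = mirfuse_species())
  expect_equal(colnames(y4), mirfuse_species())
  expect_error(encode_classes(rep("a", 5)), "two classes")
})

test_that("a predictor collinear with the class contrast gives a perfect 1-LV fit", {
  x <- matrix(c(1, 1, 1, -1, -1, -1), ncol = 1)
  m <- plsda(x, rep(c("a", "b"), each = 3), ncomp = 1)
  expect_equal(m$r2y_cum[1], 1, tolerance = 1e-10)
})

test_that("predictions at full rank coincide with multivariate OLS", {
  set.seed(51)
  x <- matrix(rnorm(25 * 4), 25, 4)
  labels <- rep(c("a", "b", "c"), length.out = 25)
  m <- plsda(x, labels, ncomp = 4)
  yhat <- predict(m, x, type = "response")
  Y <- encode_classes(labels)
  X1 <- cbind(1, x)
  ols <- X1 %*% solve(crossprod(X1), crossprod(X1, Y))
  expect_lt(max(abs(yhat - ols)), 1e-8)
})

test_that("random labels on independent X explain almost nothing", {
  set.seed(52)
  x <- matrix(rnorm(500 * 3), 500, 3)
  labels <- sample(c("a", "b"), 500, replace = TRUE)
  m <- plsda(x, labels, ncomp = 1)
  expect_lt(m$r2y_cum[1], 0.05)
})

test_that("NIPALS scores are orthogonal and R2Y(cum) is non-decreasing", {
  ds <- generate_dataset(small_config(seed = 53))
  x <- ds$caps$absorbance
  m <- plsda(x, ds$caps$meta$species, ncomp = 5)
  G <- crossprod(m$T)
  off <- abs(G - diag(diag(G)))
  norms <- sqrt(diag(G))
  expect_lt(max(off / outer(norms, norms)), 1e-8)
  expect_true(all(diff(m$r2y_cum) >= -1e-12))
})

test_that("cross-validation matches explicit PRESS enumeration on a small case", {
  set.seed(54)
  x <- matrix(rnorm(6 * 2), 6, 2)
  labels <- c("a", "a", "b", "b", "a", "b")   # both classes in every fold
  Y <- encode_classes(labels)
  cv <- plsda_cv(x, labels, ncomp_max = 1, folds = 2)
  ## oracle: same venetian-blind folds, refit by hand, accumulate PRESS
  fold_id <- ((seq_len(6) - 1L) %% 2L) + 1L
  press <- 0
  for (f in 1:2) {
    tr <- fold_id != f
    m <- plsda(x[tr, ], labels[tr], ncomp = 1)
    yhat <- predict(m, x[!tr, , drop = FALSE], type = "response")
    press <- press + sum((Y[!tr, ] - yhat)^2)
  }
  ss <- sum(sweep(Y, 2, colMeans(Y))^2)
  expect_equal(cv$q2_cum[1], 1 - press / ss, tolerance = 1e-10)
  expect_equal(cv$rmsecv[1],
               mean(sqrt(colSums((Y - 0)^2) * 0 + {
                 ## recompute per-column PRESS for the RMSECV form
                 pc <- matrix(0, 1, 2)
                 for (f in 1:2) {
                   tr <- fold_id != f
                   m <- plsda(x[tr, ], labels[tr], ncomp = 1)
                   yh <- predict(m, x[!tr, , drop = FALSE], type = "response")
                   pc <- pc + colSums((Y[!tr, ] - yh)^2)
                 }
                 c(pc / 6)
               })),
               tolerance = 1e-10)
})

test_that("perfectly predictable classes drive Q2 to 1 and RMSECV to 0", {
  x <- cbind(rep(c(5, -5), each = 10), rep(c(5, -5), each = 10))
  labels <- rep(c("a", "b"), each = 10)
  cv <- plsda_cv(x, labels, ncomp_max = 1, folds = 5)
  expect_gt(cv$q2_cum[1], 1 - 1e-8)
  expect_lt(cv$rmsecv[1], 1e-4)
})

test_that("Q2(cum) never exceeds R2Y(cum) on the same data", {
  for (seed in 1:3) {
    ds <- generate_dataset(small_config(seed = seed))
    x <- ds$caps$absorbance
    labels <- ds$caps$meta$species
    a_max <- 4
    cv <- plsda_cv(x, labels, ncomp_max = a_max, folds = 7)
    m <- plsda(x, labels, ncomp = a_max)
    expect_true(all(cv$q2_cum[seq_len(m$ncomp)] <=
                      m$r2y_cum + 1e-6))
  }
})

test_that("VIP normalisation identities hold for every fit", {
  x <- matrix(c(1, 2, 3, 4, 6, 5), ncol = 1)
  m1 <- plsda(x, rep(c("a", "b"), 3), ncomp = 1)
  expect_equal(vip(m1), 1, tolerance = 1e-12)   # p = 1
  ds <- generate_dataset(small_config(seed = 55))
  m <- plsda(ds$caps$absorbance, ds$caps$meta$species, ncomp = 3)
  expect_equal(mean(vip(m)^2), 1, tolerance = 1e-10)
})

test_that("planted informative variables score VIP > 1, noise stays below", {
  set.seed(56)
  n <- 200; p <- 40
  x <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("a", "b"), each = n / 2)
  x[, 1:5] <- x[, 1:5] + ifelse(labels == "a", 2, -2)
  m <- plsda(x, labels, ncomp = 2)
  v <- vip(m)
  expect_true(all(v[1:5] > 1))
  expect_lt(median(v[6:p]), 1)
})

test_that("RMSEE hand case and in-sample optimism versus RMSECV", {
  ## residuals (1, -1) on one Y column with n = 2 give RMSEE = 1
  m <- list(residuals = matrix(c(1, -1), 2, 1), n = 2)
  class(m) <- "plsda"
  expect_equal(rmsee(m), 1)

  ok <- 0
  for (seed in 1:5) {
    ds <- generate_dataset(small_config(seed = 60 + seed))
    x <- ds$caps$absorbance
    labels <- ds$caps$meta$species
    fit <- plsda(x, labels, ncomp = 3)
    cv <- plsda_cv(x, labels, ncomp_max = 3, folds = 7)
    if (rmsee(fit) <= cv$rmsecv[3] + 1e-8) ok <- ok + 1
  }
  expect_gte(ok, 4)   # in-sample fit beats CV essentially always
})

test_that("confusion-matrix accuracy arithmetic matches hand counts", {
  truth <- c(rep("s1", 14), rep("s2", 6), rep("s3", 10), rep("s4", 4))
  pred <- c(rep("s1", 14),                       # class 1: all correct
            rep("s2", 3), rep("s3", 2), "s4",    # class 2: 3/6
            rep("s3", 10), rep("s4", 4))
  cm <- confusion_matrix(truth, pred, levels = c("s1", "s2", "s3", "s4"))
  expect_equal(cm$total_accuracy, 100 * 31 / 34, tolerance = 1e-10)
  expect_equal(unname(cm$per_class_accuracy), c(100, 50, 100, 100))
  expect_equal(sum(cm$counts), 34)
})

test_that("class prediction is self-consistent and resolves ties to the lowest class", {
  ds <- generate_dataset(small_config(seed = 57))
  x <- ds$caps$absorbance
  labels <- ds$caps$meta$species
  m <- plsda(x, labels, ncomp = 3)
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
  expect_error(predict(m, x[, 1:10]), "columns")
  ## symmetric two-class tie: identical predicted dummies pick class 1
  mm <- list(R = matrix(0, 2, 1), C = matrix(0, 2, 1),
             x_mean = c(0, 0), x_scale = c(1, 1), y_mean = c(0.5, 0.5),
             class_levels = c("a", "b"), ncomp = 1, p = 2)
  class(mm) <- "plsda"
  expect_equal(predict(mm, matrix(c(1, 1), 1, 2)), "a")
})
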