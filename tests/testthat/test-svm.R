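test_that("the Fisher criterion matches hand computation", {
  expect_equal(fisher_score(c(3, 4, 5, 0, 1, 2), c(1, 1, 1, -1, -1, -1)),
               2.25)
  # equal class means: numerator vanishes
  expect_equal(fisher_score(c(1, 2, 3, 1, 2, 3), rep(c(1, -1), each = 3)), 0)
  # zero within-class variance with distinct means: +Inf sentinel
  expect_identical(fisher_score(c(2, 2, 0, 0), c(1, 1, -1, -1)), Inf)
  expect_error(fisher_score(1:4, rep(1, 4)), "two classes")
  # separation shrinks as within-class jitter grows
  set.seed(1)
  y <- rep(c(1, -1), each = 30)
  f_small <- fisher_score(ifelse(y > 0, 2, 0) + rnorm(60, sd = 0.01), y)
  f_big <- fisher_score(ifelse(y > 0, 2, 0) + rnorm(60, sd = 1), y)
  expect_gt(f_small, f_big)
})

test_that("roc_auc matches brute-force concordant-pair counting", {
  expect_equal(roc_auc(c(1, 1, 1, 1), c(1, 1, -1, -1))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, -1, -1))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, -1, -1))$auc, 0.75)
  set.seed(13)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    labels <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    dv <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # ties common
    expect_equal(roc_auc(dv, labels)$auc, brute_auc(dv, labels))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc curve starts at (0,0), ends at (1,1), and is monotone", {
  set.seed(14)
  dv <- rnorm(30)
  y <- rep(c(1, -1), 15)
  roc <- roc_auc(dv, y)$roc
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  dv <- rnorm(40)
  y <- sample(c(1, -1), 40, replace = TRUE, prob = c(0.4, 0.6))
  ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y),
                                        predictor = dv, quiet = TRUE,
                                        direction = "<", levels = c("-1", "1"))))
  expect_equal(roc_auc(dv, y)$auc, ref, tolerance = 1e-12)
})

test_that("LOOCV SVM is perfect on well-separated classes", {
  set.seed(16)
  n <- 40
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * 6), n) + outer(y, rep(2, 6))  # 4-sigma separation
  colnames(X) <- paste0("e", 1:6)
  res <- loocv_svm(X, y, k = 6)
  expect_equal(mean(res$predicted == y), 1)
  expect_equal(roc_auc(res$decision, y)$auc, 1)
})

test_that("flipping every label flips every prediction", {
  set.seed(17)
  n <- 24
  y <- rep(c(1, -1), n / 2)
  X <- matrix(rnorm(n * 5), n)
  X[, 1] <- X[, 1] + y
  colnames(X) <- paste0("e", 1:5)
  a <- loocv_svm(X, y, k = 3)
  b <- loocv_svm(X, -y, k = 3)
  expect_equal(a$predicted, -b$predicted)
})

test_that("fold-wise ranking cannot see the held-out subject", {
  # feature 1 separates the classes; feature 2 is constant except for the
  # held-out subject, where it is enormous.  With fold-wise ranking the
  # training fold sees a constant feature 2 (score 0), so feature 1 must be
  # selected and every prediction is correct.  Leaking the held-out row
  # into the ranking would give feature 2 an infinite score instead.
  set.seed(18)
  n <- 20
  y <- rep(c(1, -1), n / 2)
  X <- cbind(e1 = y * 2 + rnorm(n, sd = 0.1), e2 = 0)
  for (i in seq_len(n)) {
    Xi <- X
    Xi[i, "e2"] <- 1e6 * y[i]
    fold <- cbtcloops:::loocv_fold(Xi, y, i, k = 1, ranking = "fold",
                                   global_rank = NULL, C = 1)
    expect_equal(fold$pred, y[i])
  }
})

test_that("accuracy curve reports per-k accuracies and parsimonious best_k", {
  set.seed(19)
  n <- 24
  y <- rep(c(1, -1), n / 2)
  X <- matrix(rnorm(n * 8), n)
  X[, 3] <- X[, 3] + y * 3
  colnames(X) <- paste0("e", 1:8)
  res <- accuracy_curve(X, y, k_grid = c(1, 2, 4, 8))
  expect_s3_class(res, "cbtc_svm")
  expect_length(res$accuracy_by_k, 4)
  expect_true(all(res$accuracy_by_k >= 0 & res$accuracy_by_k <= 1))
  expect_true(all(c(res$accuracy, res$sensitivity, res$specificity,
                    res$auc) >= 0))
  # the separating feature is found immediately: ties broken to smallest k
  expect_equal(res$best_k,
               as.integer(names(which(res$accuracy_by_k ==
                                      max(res$accuracy_by_k)))[1]))
})

test_that("pure-noise features classify at chance", {
  set.seed(20)
  accs <- replicate(10, {
    y <- rep(c(1, -1), 8)
    X <- matrix(rnorm(16 * 6), 16, dimnames = list(NULL, paste0("e", 1:6)))
    mean(loocv_svm(X, y, k = 3)$predicted == y)
  })
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("the AUC permutation test is seeded and directional", {
  set.seed(21)
  n <- 16
  y <- rep(c(1, -1), n / 2)
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("e", 1:4)))
  p1 <- permutation_test_auc(X, y, k = 2, n_perm = 30, seed = 99)
  p2 <- permutation_test_auc(X, y, k = 2, n_perm = 30, seed = 99)
  expect_identical(p1$p, p2$p)
  expect_length(p1$perm_auc, 30)

  # uninformative constant features: every AUC (observed and permuted) is a
  # total tie at 0.5, and the >= proportion is exactly 1
  Xs <- matrix(1, n, 2, dimnames = list(NULL, c("e1", "e2")))
  pa <- permutation_test_auc(Xs, y, k = 1, n_perm = 50, seed = 7)
  expect_equal(pa$p, 1)
  # add-one variant can never be exactly zero
  pb <- permutation_test_auc(X, y, k = 2, n_perm = 30, seed = 1,
                             variant = "add-one")
  expect_gt(pb$p, 0)
})

test_that("svm_classify drives the full workflow from group labels", {
  set.seed(22)
  coh <- small_cohort()
  fc <- small_fc_loops()
  res <- svm_classify(fc, coh$subjects$group, k_grid = c(1, 4, 8),
                      n_perm = 20, seed = 5)
  expect_s3_class(res, "cbtc_svm")
  expect_true(res$permutation_p >= 0 && res$permutation_p <= 1)
  expect_output(print(res), "Linear SVM")
})

test_that("input contracts are enforced", {
  X <- matrix(rnorm(12), 4, dimnames = list(NULL, c("a", "b", "c")))
  y <- c(1, 1, -1, -1)
  expect_error(loocv_svm(X, y, k = 5), "k must lie")
  expect_error(loocv_svm(X[1:3, ], y[1:3], k = 1), "at least 4")
  expect_error(loocv_svm(X, c(1, 1, 1, -1), k = 1), "2 subjects per class")
})
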