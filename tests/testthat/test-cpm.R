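test_that("edge selection finds perfectly coupled edges with the right sign", {
  fc <- noise_fc(20, n_edges = 10, seed = 30)
  beh <- fc[, 3]
  sel <- select_edges(fc, beh)
  expect_true(colnames(fc)[3] %in% sel$positive)
  sel2 <- select_edges(fc, -fc[, 5])
  expect_true(colnames(fc)[5] %in% sel2$negative)
  expect_length(intersect(sel$positive, sel$negative), 0)
  expect_error(select_edges(fc, rep(1, 20)), "constant")
  expect_error(select_edges(fc[1:3, ], beh[1:3]), "at least 4")
})

test_that("null edge selection is calibrated to the threshold", {
  set.seed(31)
  hits <- 0
  total <- 0
  for (rep in 1:50) {
    fc <- matrix(rnorm(30 * 40), 30,
                 dimnames = list(NULL, paste0("e", 1:40)))
    beh <- rnorm(30)
    sel <- select_edges(fc, beh, p_sel = 0.05)
    hits <- hits + length(sel$positive) + length(sel$negative)
    total <- total + 40
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)
})

test_that("network strength is the additive sum over the edge set", {
  z <- c(e1 = 0.3, e2 = 0.5, e3 = -0.2)
  expect_equal(network_strength(z, character(0)), 0)
  expect_equal(network_strength(z, "e1"), 0.3)
  expect_equal(network_strength(z, c("e1", "e2")), 0.8)
  expect_error(network_strength(z, "zz"), "not in FC support")
  m <- rbind(z, z * 2)
  expect_equal(unname(network_strength(m, c("e1", "e3"))), c(0.1, 0.2))
})

test_that("Spearman evaluation matches rank-formula hand computation", {
  expect_equal(evaluate_spearman(1:4, 1:4), 1)
  expect_equal(evaluate_spearman(1:4, 4:1), -1)
  expect_equal(evaluate_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(evaluate_spearman(rep(1, 4), 1:4), "constant")
  expect_error(evaluate_spearman(1:3, 1:4), "lengths differ")
})

test_that("CPM recovers a planted positive edge with near-perfect rank r", {
  set.seed(32)
  n <- 40
  fc <- matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("e", 1:20)))
  beh <- 2 * fc[, 7] + rnorm(n, sd = 0.1)
  fit <- loocv_cpm(fc, beh, "positive")
  expect_gte(evaluate_spearman(fit$predicted, beh), 0.9)
  sel_freq <- mean(vapply(fit$selections, function(s) "e7" %in% s$positive,
                          logical(1)))
  expect_equal(sel_freq, 1)
  wr <- well_represented(fit$selections, min_frac = 1)
  expect_true("e7" %in% wr$edge[wr$sign == "positive"])
})

test_that("a planted negative edge lands in the negative network", {
  set.seed(33)
  n <- 40
  fc <- matrix(rnorm(n * 15), n, dimnames = list(NULL, paste0("e", 1:15)))
  beh <- -1.5 * fc[, 4] + rnorm(n, sd = 0.3)
  fit <- loocv_cpm(fc, beh, "negative")
  freq <- mean(vapply(fit$selections, function(s) "e4" %in% s$negative,
                      logical(1)))
  expect_gte(freq, 0.9)
  expect_gt(evaluate_spearman(fit$predicted, beh), 0.5)
})

test_that("folds that select nothing fall back to the training mean", {
  set.seed(34)
  fc <- matrix(rnorm(8 * 5), 8, dimnames = list(NULL, paste0("e", 1:5)))
  beh <- rnorm(8)
  fit <- loocv_cpm(fc, beh, "positive", p_sel = 1e-9)
  expect_true(all(fit$flagged))
  expect_equal(unname(fit$predicted[1]), mean(beh[-1]))
})

test_that("the held-out subject never influences its own fold's selection", {
  set.seed(35)
  n <- 12
  fc <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("e", 1:8)))
  beh <- rnorm(n)
  i <- 5
  beh2 <- beh
  beh2[i] <- beh[i] + 100
  fit1 <- loocv_cpm(fc, beh, "positive")
  fit2 <- loocv_cpm(fc, beh2, "positive")
  expect_identical(fit1$selections[[i]], fit2$selections[[i]])
  fc2 <- fc
  fc2[i, ] <- fc[i, ] + 50
  fit3 <- loocv_cpm(fc2, beh, "positive")
  expect_identical(fit1$selections[[i]], fit3$selections[[i]])
})

test_that("both combined-model parameterisations produce predictions", {
  set.seed(36)
  n <- 30
  fc <- matrix(rnorm(n * 12), n, dimnames = list(NULL, paste0("e", 1:12)))
  beh <- 1.5 * fc[, 1] - 1.5 * fc[, 2] + rnorm(n, sd = 0.3)
  two <- loocv_cpm(fc, beh, "combined", combined_form = "two-predictor")
  sd_ <- loocv_cpm(fc, beh, "combined", combined_form = "sum-diff")
  expect_gt(evaluate_spearman(two$predicted, beh), 0.7)
  expect_gt(evaluate_spearman(sd_$predicted, beh), 0.7)
})

test_that("the CPM permutation test is seeded and detects planted signal", {
  set.seed(37)
  n <- 24
  fc <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("e", 1:10)))
  beh <- 2 * fc[, 2] + rnorm(n, sd = 0.2)
  a <- permutation_test_cpm(fc, beh, "positive", n_perm = 50, seed = 3)
  b <- permutation_test_cpm(fc, beh, "positive", n_perm = 50, seed = 3)
  expect_identical(a$p, b$p)
  expect_lte(a$p, 1 / 50 + 1e-12)
  expect_gt(a$observed_r, 0.8)
})

test_that("well_represented applies the frequency threshold with signs", {
  sels <- list(list(positive = c("a", "b"), negative = "c"),
               list(positive = "a", negative = "c"),
               list(positive = "a", negative = character(0)))
  wr <- well_represented(sels, min_frac = 1)
  expect_equal(wr$edge[wr$sign == "positive"], "a")
  expect_false("c" %in% wr$edge)
  wr2 <- well_represented(sels, min_frac = 0.6)
  expect_true(all(c("a", "c") %in% wr2$edge))
  expect_false("b" %in% wr2$edge)
  expect_error(well_represented(list()), "no fold selections")
})

test_that("cpm_predict assembles all modes with stability reporting", {
  set.seed(38)
  n <- 24
  fc <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("e", 1:10)))
  beh <- 2 * fc[, 1] + rnorm(n, sd = 0.2)
  res <- cpm_predict(fc, beh, n_perm = 20, seed = 4)
  expect_s3_class(res, "cbtc_cpm")
  expect_named(res$modes, c("positive", "negative", "combined"))
  expect_gt(res$modes$positive$spearman_r, 0.8)
  expect_true("e1" %in% res$well_represented$edge)
  expect_output(print(res), "Connectome-based")
})
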