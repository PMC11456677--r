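# Case-control classification: F-score (Fisher criterion) feature ranking,
# linear SVM, leave-one-out cross-validation, accuracy as a function of the
# number of top-ranked connections, ROC/AUC, and label-permutation inference.
#
# Labels follow the +1 = patient, -1 = control convention throughout.

#' Fisher criterion score of one feature
#'
#' `F = ((m_pos - m)^2 + (m_neg - m)^2) / (s_pos^2 + s_neg^2)` with class
#' means `m_pos`, `m_neg`, grand mean `m`, and unbiased within-class
#' variances.  A zero denominator with distinct class means yields `Inf`
#' (such a feature separates the classes perfectly and ranks first).
#'
#' @param x Numeric feature values.
#' @param labels Vector with both classes present (+1/-1 or two levels).
#' @return Nonnegative score (possibly `Inf`).
#' @examples
#' fisher_score(c(3, 4, 5, 0, 1, 2), c(1, 1, 1, -1, -1, -1))  # 2.25
#' @export
fisher_score <- function(x, labels) {
  cls <- unique(labels)
  if (length(cls) != 2L) stop_cbtc("labels must contain exactly two classes")
  a <- x[labels == cls[1L]]
  b <- x[labels == cls[2L]]
  m <- mean(x)
  num <- (mean(a) - m)^2 + (mean(b) - m)^2
  den <- stats::var(a) + stats::var(b)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

# Vectorised Fisher scores over the columns of a feature matrix.
fisher_scores <- function(X, labels) {
  cls <- unique(labels)
  if (length(cls) != 2L) stop_cbtc("labels must contain exactly two classes")
  A <- X[labels == cls[1L], , drop = FALSE]
  B <- X[labels == cls[2L], , drop = FALSE]
  m <- colMeans(X)
  num <- (colMeans(A) - m)^2 + (colMeans(B) - m)^2
  den <- col_vars(A) + col_vars(B)
  out <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  names(out) <- colnames(X)
  out
}

#' ROC curve and AUC from decision values
#'
#' AUC equals the Mann-Whitney statistic of the decision values (concordant
#' pairs, ties counted 1/2); the ROC curve is a threshold sweep over the
#' observed decision values.
#'
#' @param decision_values Numeric scores, larger = more patient-like.
#' @param labels +1 (patient) / -1 (control).
#' @return List with `roc` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(decision_values, labels) {
  pos <- labels > 0
  if (!any(pos) || all(pos)) stop_cbtc("both classes must be present")
  r <- rank(decision_values)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(decision_values), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(th, function(t) mean(decision_values[!pos] >= t),
                 numeric(1)),
    tpr = vapply(th, function(t) mean(decision_values[pos] >= t),
                 numeric(1)))
  list(roc = roc, auc = auc)
}

#' Leave-one-out cross-validated linear SVM on top-k ranked connections
#'
#' For each held-out subject: standardise features using training-fold mean
#' and sd only, rank features by Fisher score (within the training fold when
#' `ranking = "fold"`, once on the full sample when `ranking = "global"` --
#' the latter mirrors a single global ranking but leaks the held-out label
#' into the ranking), keep the top `k`, train a linear SVM with cost `C`,
#' and record the held-out prediction and decision value (oriented so that
#' positive means patient).
#'
#' @param features Subjects x connections numeric matrix.
#' @param labels +1 (patient) / -1 (control), both classes with >= 2
#'   subjects, `n >= 4`.
#' @param k Number of top-ranked connections, `1 <= k <= ncol(features)`.
#' @param ranking `"fold"` (default, leakage-safe) or `"global"`.
#' @param C SVM cost (default 1).
#' @return List with `predicted` (+1/-1 per subject) and `decision`
#'   (numeric per subject).
#' @export
loocv_svm <- function(features, labels, k,
                      ranking = c("fold", "global"), C = 1) {
  ranking <- match.arg(ranking)
  n <- nrow(features)
  if (n < 4L) stop_cbtc("need at least 4 subjects")
  if (sum(labels > 0) < 2L || sum(labels < 0) < 2L) {
    stop_cbtc("need at least 2 subjects per class")
  }
  if (k < 1L || k > ncol(features)) {
    stop_cbtc("k must lie in 1..", ncol(features))
  }
  global_rank <- if (ranking == "global") {
    order(fisher_scores(features, labels), decreasing = TRUE)
  } else NULL
  pred <- numeric(n)
  dec <- numeric(n)
  for (i in seq_len(n)) {
    fold <- loocv_fold(features, labels, i, k, ranking, global_rank, C)
    pred[i] <- fold$pred
    dec[i] <- fold$dec
  }
  list(predicted = pred, decision = dec)
}

col_vars <- function(M) {
  n <- nrow(M)
  (colSums(M^2) - n * colMeans(M)^2) / (n - 1)
}

# One LOOCV fold: standardise, rank, train, predict the held-out subject.
loocv_fold <- function(features, labels, i, k, ranking, global_rank, C) {
  tr_x <- features[-i, , drop = FALSE]
  tr_y <- labels[-i]
  mu <- colMeans(tr_x)
  sdv <- sqrt(pmax(col_vars(tr_x), 0))
  sdv[sdv == 0] <- 1
  tr_x <- t((t(tr_x) - mu) / sdv)
  te_x <- (features[i, ] - mu) / sdv
  ord <- if (identical(ranking, "fold")) {
    order(fisher_scores(tr_x, tr_y), decreasing = TRUE)
  } else {
    global_rank
  }
  keep <- ord[seq_len(k)]
  fit <- e1071::svm(tr_x[, keep, drop = FALSE], factor(tr_y),
                    kernel = "linear", cost = C, scale = FALSE)
  # linear decision value f(x) = x . w - rho, oriented by libsvm toward the
  # first training label (order of appearance); flip so positive always
  # means +1 (patient)
  w <- crossprod(fit$coefs, fit$SV)
  d <- sum(te_x[keep] * w) - fit$rho
  if (fit$levels[fit$labels[1L]] == "-1") d <- -d
  list(pred = if (d >= 0) 1 else -1, dec = d)
}

#' LOOCV accuracy curve over the number of top-ranked connections
#'
#' Sweeps `k` over `k_grid`, reporting LOOCV accuracy per `k`; `best_k` is
#' the smallest `k` attaining the maximum (parsimony on ties).  Sensitivity,
#' specificity, ROC and AUC are computed from the held-out predictions and
#' decision values at `best_k`.
#'
#' @inheritParams loocv_svm
#' @param k_grid Integer vector of `k` values (default `1:ncol(features)`).
#' @return A `cbtc_svm` object: `accuracy_by_k`, `best_k`, `accuracy`,
#'   `sensitivity`, `specificity`, `roc`, `auc`, `ranking`, `C`, `n`.
#' @export
accuracy_curve <- function(features, labels, ranking = c("fold", "global"),
                           C = 1, k_grid = NULL) {
  ranking <- match.arg(ranking)
  K <- ncol(features)
  k_grid <- as.integer(k_grid %||% seq_len(K))
  if (any(k_grid < 1L | k_grid > K)) stop_cbtc("k_grid must lie in 1..", K)
  n <- nrow(features)
  if (n < 4L) stop_cbtc("need at least 4 subjects")
  if (sum(labels > 0) < 2L || sum(labels < 0) < 2L) {
    stop_cbtc("need at least 2 subjects per class")
  }
  global_rank <- if (ranking == "global") {
    order(fisher_scores(features, labels), decreasing = TRUE)
  } else NULL
  pred <- matrix(NA_real_, n, length(k_grid))
  dec <- matrix(NA_real_, n, length(k_grid))
  for (i in seq_len(n)) {
    for (j in seq_along(k_grid)) {
      fold <- loocv_fold(features, labels, i, k_grid[j], ranking,
                         global_rank, C)
      pred[i, j] <- fold$pred
      dec[i, j] <- fold$dec
    }
  }
  acc <- colMeans(pred == labels)
  names(acc) <- as.character(k_grid)
  jbest <- which.max(acc)  # first maximum = smallest k on ties
  best_k <- k_grid[jbest]
  pb <- pred[, jbest]
  db <- dec[, jbest]
  ra <- roc_auc(db, labels)
  structure(list(
    accuracy_by_k = acc, best_k = best_k, accuracy = unname(acc[jbest]),
    sensitivity = mean(pb[labels > 0] == 1),
    specificity = mean(pb[labels < 0] == -1),
    roc = ra$roc, auc = ra$auc, predicted = pb, decision = db,
    ranking = ranking, C = C, n = n), class = "cbtc_svm")
}

#' Label-permutation test of the LOOCV AUC
#'
#' Re-runs the full LOOCV classifier at fixed `k` under `n_perm` random
#' permutations of the class labels and reports the proportion of permuted
#' AUC values greater than or equal to the observed AUC.  The literal
#' proportion can be exactly 0; `variant = "add-one"` gives the
#' `(b + 1) / (n_perm + 1)` estimate, which cannot.
#'
#' @inheritParams loocv_svm
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed for the permutation stream.
#' @param variant `"proportion"` (default) or `"add-one"`.
#' @return List with `p`, `observed_auc`, `perm_auc` (length `n_perm`).
#' @export
permutation_test_auc <- function(features, labels, k, n_perm = 5000L,
                                 seed = 1L, ranking = c("fold", "global"),
                                 C = 1, variant = c("proportion",
                                                    "add-one")) {
  ranking <- match.arg(ranking)
  variant <- match.arg(variant)
  obs <- roc_auc(loocv_svm(features, labels, k, ranking, C)$decision,
                 labels)$auc
  perm_auc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(labels)
      if (sum(yp > 0) < 2L || sum(yp < 0) < 2L) return(NA_real_)
      roc_auc(loocv_svm(features, yp, k, ranking, C)$decision, yp)$auc
    }, numeric(1))
  })
  perm_auc <- perm_auc[!is.na(perm_auc)]
  b <- sum(perm_auc >= obs)
  p <- if (variant == "proportion") b / length(perm_auc)
       else (b + 1) / (length(perm_auc) + 1)
  list(p = p, observed_auc = obs, perm_auc = perm_auc, variant = variant)
}

#' Classify a cohort's FC vectors with the full SVM workflow
#'
#' Convenience wrapper: accuracy curve over `k_grid`, then a label
#' permutation test of the AUC at `best_k`.
#'
#' @param fc Subjects x edges Fisher-z matrix.
#' @param group `"patient"`/`"control"` per row (mapped to +1/-1).
#' @inheritParams accuracy_curve
#' @inheritParams permutation_test_auc
#' @return A `cbtc_svm` object with `permutation_p`, `n_perm` and `seed`
#'   fields added.
#' @export
svm_classify <- function(fc, group, ranking = c("fold", "global"), C = 1,
                         k_grid = NULL, n_perm = 5000L, seed = 1L,
                         variant = c("proportion", "add-one")) {
  ranking <- match.arg(ranking)
  labels <- ifelse(as.character(group) == "patient", 1, -1)
  res <- accuracy_curve(fc, labels, ranking = ranking, C = C,
                        k_grid = k_grid)
  pt <- permutation_test_auc(fc, labels, k = res$best_k, n_perm = n_perm,
                             seed = seed, ranking = ranking, C = C,
                             variant = variant)
  res$permutation_p <- pt$p
  res$n_perm <- length(pt$perm_auc)
  res$seed <- seed
  res
}

#' @export
print.cbtc_svm <- function(x, ...) {
  cat("Linear SVM (LOOCV, ", x$ranking, " ranking, C = ", x$C, ")\n",
      sep = "")
  cat(sprintf("  best k = %d: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n",
              x$best_k, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity, x$auc))
  if (!is.null(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g (%d label permutations)\n",
                x$permutation_p, x$n_perm))
  }
  invisible(x)
}
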