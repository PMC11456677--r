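# Connectome-based predictive modelling (CPM) of upper-limb motor scores.
#
# Within each leave-one-out fold, edges whose Fisher-z values correlate with
# behaviour in the training subjects (p below a selection threshold) are
# split into positive and negative sets; the summed strength of each set is
# the predictor of a linear model fitted on the training subjects and
# applied to the held-out subject.  Performance is the Spearman correlation
# between predicted and observed scores; inference is by behaviour-shuffling
# permutation with a full LOOCV re-run per shuffle.

# Vectorised edge-behaviour correlations with two-sided p-values (t
# approximation, standard for both Pearson and rank-transformed Spearman).
edge_behavior_corr <- function(fc, behavior,
                               corr_type = c("pearson", "spearman")) {
  corr_type <- match.arg(corr_type)
  n <- length(behavior)
  if (corr_type == "spearman") {
    fc <- apply(fc, 2L, rank)
    behavior <- rank(behavior)
  }
  r <- suppressWarnings(as.numeric(stats::cor(fc, behavior)))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(edge = colnames(fc), r = r, p = p, stringsAsFactors = FALSE)
}

#' Select behaviourally correlated edges
#'
#' @param train_fc Training subjects x edges Fisher-z matrix (>= 4 rows).
#' @param train_behavior Behaviour scores, nonconstant.
#' @param p_sel Selection threshold on the correlation p-value (default
#'   0.05).
#' @param corr_type `"pearson"` (default) or `"spearman"`.
#' @return List with `positive` and `negative` edge-id vectors (disjoint:
#'   positive requires `r > 0`, negative `r < 0`, both `p < p_sel`).
#' @export
select_edges <- function(train_fc, train_behavior, p_sel = 0.05,
                         corr_type = c("pearson", "spearman")) {
  corr_type <- match.arg(corr_type)
  if (nrow(train_fc) < 4L) stop_cbtc("need at least 4 training subjects")
  if (stats::sd(train_behavior) == 0) {
    stop_cbtc("behaviour is constant in the training set")
  }
  ec <- edge_behavior_corr(train_fc, train_behavior, corr_type)
  list(positive = ec$edge[ec$r > 0 & ec$p < p_sel],
       negative = ec$edge[ec$r < 0 & ec$p < p_sel])
}

#' Summed network strength over an edge set
#'
#' @param fc_vector Named Fisher-z vector (or subjects x edges matrix, in
#'   which case a per-subject vector is returned).
#' @param edge_set Edge ids (subset of the vector's names); empty set gives
#'   0.
#' @return Scalar (or per-subject vector) strength.
#' @export
network_strength <- function(fc_vector, edge_set) {
  if (is.matrix(fc_vector)) {
    if (!length(edge_set)) return(numeric(nrow(fc_vector)))
    miss <- setdiff(edge_set, colnames(fc_vector))
    if (length(miss)) stop_cbtc("edge not in FC support: ", miss[1L])
    return(rowSums(fc_vector[, edge_set, drop = FALSE]))
  }
  if (!length(edge_set)) return(0)
  miss <- setdiff(edge_set, names(fc_vector))
  if (length(miss)) stop_cbtc("edge not in FC support: ", miss[1L])
  sum(fc_vector[edge_set])
}

#' Leave-one-out cross-validated CPM prediction
#'
#' Per fold: select edges on the training subjects only, compute network
#' strengths, fit a least-squares linear model of behaviour on strength
#' (`positive`/`negative`: one predictor; `combined`: positive and negative
#' strengths as two predictors), and predict the held-out subject.  A fold
#' selecting no edges for its mode predicts the training-mean behaviour and
#' is flagged.
#'
#' @param fc Subjects x edges Fisher-z matrix (`n >= 5`).
#' @param behavior Behaviour scores aligned with rows of `fc`.
#' @param mode `"positive"`, `"negative"` or `"combined"`.
#' @param p_sel,corr_type Edge-selection parameters (see [select_edges()]).
#' @param combined_form `"two-predictor"` (default: positive and negative
#'   strengths enter as separate regressors) or `"sum-diff"` (single
#'   regressor, positive minus negative strength).
#' @return List with `predicted` (per subject), `selections` (per fold,
#'   `positive`/`negative` edge sets) and `flagged` (folds with no edges).
#' @export
loocv_cpm <- function(fc, behavior,
                      mode = c("positive", "negative", "combined"),
                      p_sel = 0.05, corr_type = c("pearson", "spearman"),
                      combined_form = c("two-predictor", "sum-diff")) {
  mode <- match.arg(mode)
  corr_type <- match.arg(corr_type)
  combined_form <- match.arg(combined_form)
  n <- nrow(fc)
  if (n < 5L) stop_cbtc("need at least 5 subjects")
  if (length(behavior) != n) stop_cbtc("behavior length must match fc rows")
  predicted <- numeric(n)
  flagged <- logical(n)
  selections <- vector("list", n)
  for (i in seq_len(n)) {
    tr_fc <- fc[-i, , drop = FALSE]
    tr_b <- behavior[-i]
    sel <- select_edges(tr_fc, tr_b, p_sel, corr_type)
    selections[[i]] <- sel
    use <- switch(mode,
                  positive = list(sel$positive),
                  negative = list(sel$negative),
                  combined = if (combined_form == "two-predictor") {
                    list(sel$positive, sel$negative)
                  } else {
                    list(c(sel$positive, sel$negative))
                  })
    if (mode == "combined" && combined_form == "sum-diff") {
      s_tr <- network_strength(tr_fc, sel$positive) -
        network_strength(tr_fc, sel$negative)
      s_te <- network_strength(fc[i, ], sel$positive) -
        network_strength(fc[i, ], sel$negative)
      X <- cbind(s_tr)
      xte <- s_te
    } else {
      keep <- vapply(use, length, integer(1)) > 0L
      if (!any(keep)) {
        predicted[i] <- mean(tr_b)
        flagged[i] <- TRUE
        next
      }
      X <- do.call(cbind, lapply(use[keep], function(es) {
        network_strength(tr_fc, es)
      }))
      xte <- vapply(use[keep], function(es) {
        network_strength(fc[i, ], es)
      }, numeric(1))
    }
    if (all(apply(X, 2L, stats::sd) == 0)) {
      predicted[i] <- mean(tr_b)
      flagged[i] <- TRUE
      next
    }
    fit <- stats::lm.fit(cbind(1, X), tr_b)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    predicted[i] <- sum(beta * c(1, xte))
  }
  names(predicted) <- rownames(fc)
  list(predicted = predicted, selections = selections, flagged = flagged)
}

#' Spearman evaluation of predicted against observed scores
#'
#' Spearman rank correlation with average-rank tie handling.
#'
#' @param predicted,observed Numeric vectors, length >= 3, nonconstant.
#' @return Correlation in `[-1, 1]`.
#' @export
evaluate_spearman <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop_cbtc("lengths differ")
  if (length(predicted) < 3L) stop_cbtc("need at least 3 subjects")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop_cbtc("constant vector: Spearman correlation undefined")
  }
  stats::cor(predicted, observed, method = "spearman")
}

#' Behaviour-shuffling permutation test of CPM performance
#'
#' Shuffles the behaviour scores `n_perm` times, re-runs the full LOOCV CPM
#' per shuffle, and reports the proportion of permuted Spearman correlations
#' greater than or equal to the observed one.
#'
#' @inheritParams loocv_cpm
#' @param n_perm Number of shuffles (default 5000).
#' @param seed Integer seed for the shuffle stream.
#' @return List with `p`, `observed_r`, `perm_r`.
#' @export
permutation_test_cpm <- function(fc, behavior,
                                 mode = c("positive", "negative",
                                          "combined"),
                                 n_perm = 5000L, seed = 1L, p_sel = 0.05,
                                 corr_type = c("pearson", "spearman"),
                                 combined_form = c("two-predictor",
                                                   "sum-diff")) {
  mode <- match.arg(mode)
  corr_type <- match.arg(corr_type)
  combined_form <- match.arg(combined_form)
  obs_fit <- loocv_cpm(fc, behavior, mode, p_sel, corr_type, combined_form)
  obs_r <- evaluate_spearman(obs_fit$predicted, behavior)
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      bp <- sample(behavior)
      pr <- loocv_cpm(fc, bp, mode, p_sel, corr_type,
                      combined_form)$predicted
      if (stats::sd(pr) == 0) return(0)
      evaluate_spearman(pr, bp)
    }, numeric(1))
  })
  list(p = mean(perm_r >= obs_r), observed_r = obs_r, perm_r = perm_r)
}

#' Edges most consistently selected across folds
#'
#' @param per_fold_selections List of per-fold `positive`/`negative` edge
#'   sets (as recorded by [loocv_cpm()]).
#' @param min_frac Minimum fold-selection frequency (default 1.0 = selected
#'   in every fold).
#' @return Data frame with columns `edge`, `sign`, `frequency`, sorted by
#'   decreasing frequency.
#' @export
well_represented <- function(per_fold_selections, min_frac = 1.0) {
  n <- length(per_fold_selections)
  if (!n) stop_cbtc("no fold selections recorded")
  freq_of <- function(sign) {
    tab <- table(unlist(lapply(per_fold_selections, `[[`, sign)))
    if (!length(tab)) return(NULL)
    data.frame(edge = names(tab), sign = sign,
               frequency = as.numeric(tab) / n, stringsAsFactors = FALSE)
  }
  out <- rbind(freq_of("positive"), freq_of("negative"))
  if (is.null(out)) {
    return(data.frame(edge = character(), sign = character(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  out <- out[out$frequency >= min_frac, , drop = FALSE]
  out <- out[order(-out$frequency, out$edge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full CPM workflow over one or more modes
#'
#' Runs LOOCV prediction, Spearman evaluation, the behaviour-shuffling
#' permutation test, and fold-stability reporting for each requested mode.
#'
#' @inheritParams loocv_cpm
#' @inheritParams permutation_test_cpm
#' @param modes Modes to run (default all three).
#' @param min_frac Fold-selection frequency threshold for the
#'   well-represented report (default 1.0).
#' @return A `cbtc_cpm` object: per mode, `predicted`, `spearman_r`,
#'   `permutation_p`, `flagged_folds`; plus `well_represented`, `observed`
#'   behaviour and the settings used.
#' @export
cpm_predict <- function(fc, behavior,
                        modes = c("positive", "negative", "combined"),
                        p_sel = 0.05,
                        corr_type = c("pearson", "spearman"),
                        combined_form = c("two-predictor", "sum-diff"),
                        n_perm = 5000L, seed = 1L, min_frac = 1.0) {
  corr_type <- match.arg(corr_type)
  combined_form <- match.arg(combined_form)
  modes <- match.arg(modes, c("positive", "negative", "combined"),
                     several.ok = TRUE)
  res <- list()
  selections <- NULL
  for (m in modes) {
    fit <- loocv_cpm(fc, behavior, m, p_sel, corr_type, combined_form)
    selections <- selections %||% fit$selections
    pt <- permutation_test_cpm(fc, behavior, m, n_perm = n_perm,
                               seed = seed, p_sel = p_sel,
                               corr_type = corr_type,
                               combined_form = combined_form)
    res[[m]] <- list(predicted = fit$predicted,
                     spearman_r = pt$observed_r,
                     permutation_p = pt$p,
                     flagged_folds = sum(fit$flagged))
  }
  structure(list(modes = res,
                 well_represented = well_represented(selections, min_frac),
                 observed = behavior, p_sel = p_sel,
                 corr_type = corr_type, combined_form = combined_form,
                 n_perm = n_perm, seed = seed, min_frac = min_frac),
            class = "cbtc_cpm")
}

#' @export
print.cbtc_cpm <- function(x, ...) {
  cat("Connectome-based predictive modelling (LOOCV, ", x$corr_type,
      " selection at p < ", x$p_sel, ", ", x$n_perm,
      " behaviour shuffles)\n", sep = "")
  for (m in names(x$modes)) {
    r <- x$modes[[m]]
    cat(sprintf("  %-9s r = %.3f, permutation p = %.4g%s\n", m,
                r$spearman_r, r$permutation_p,
                if (r$flagged_folds > 0) {
                  paste0(" (", r$flagged_folds, " empty fold(s))")
                } else ""))
  }
  wr <- x$well_represented
  if (nrow(wr)) {
    cat("  edges selected in >= ", 100 * x$min_frac, "% of folds:\n",
        sep = "")
    for (i in seq_len(nrow(wr))) {
      cat(sprintf("    %s (%s, %.0f%%)\n", wr$edge[i], wr$sign[i],
                  100 * wr$frequency[i]))
    }
  }
  invisible(x)
}
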