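# Group-level statistics: demographic tests (chi-square on sex, Mann-Whitney
# U on age) and edge-wise two-sample comparison of Fisher-z FC with
# Benjamini-Hochberg FDR correction.

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square WITHOUT continuity correction (df = 1).  The continuity
#' correction is deliberately off: demographic sex-by-group tables in this
#' field are conventionally reported uncorrected.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return List with `chi2` and `p`.
#' @examples
#' chi2_2x2(matrix(c(35, 36, 29, 28), 2))  # chi2 = 0.032, p = 0.859
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_cbtc("expected a 2x2 table")
  if (any(table < 0)) stop_cbtc("negative count")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_cbtc("zero margin: chi-square undefined")
  }
  # small expected counts only trigger chisq.test's approximation warning;
  # the statistic itself is the closed form either way
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Mann-Whitney U test with normal approximation
#'
#' Computes the U statistic for `xs` (number of `(x, y)` pairs with `x > y`,
#' ties counted 1/2) and a standardised `z` using the normal approximation
#' with tie correction, as statistical packages print it; two-sided p from
#' the normal.
#'
#' @param xs,ys Nonempty numeric samples.
#' @return List with `U`, `z`, `p`.
#' @export
mann_whitney <- function(xs, ys) {
  if (!length(xs) || !length(ys)) stop_cbtc("both samples must be nonempty")
  n1 <- length(xs)
  n2 <- length(ys)
  r <- rank(c(xs, ys))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(c(xs, ys))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, z = 0, p = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, order-preserving
#' with respect to the input indexing.
#'
#' @param pvec Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvec) {
  if (any(!is.finite(pvec)) || any(pvec < 0) || any(pvec > 1)) {
    stop_cbtc("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvec, method = "BH")
}

#' Demographic group comparison
#'
#' Chi-square (no continuity correction) on sex x group and Mann-Whitney U
#' on age (patients vs controls).
#'
#' @param subjects Phenotype data frame with columns `group`, `sex`, `age`.
#' @return List with `chi2` (`chi2`, `p`) and `mw` (`U`, `z`, `p`).
#' @export
demographic_stats <- function(subjects) {
  tab <- table(factor(subjects$group, c("patient", "control")),
               factor(subjects$sex, c("male", "female")))
  pat <- subjects$age[subjects$group == "patient"]
  ctl <- subjects$age[subjects$group == "control"]
  list(chi2 = chi2_2x2(tab), mw = mann_whitney(pat, ctl))
}

#' Edge-wise two-sample comparison of Fisher-z FC
#'
#' Runs a two-sample t-test per edge (Welch by default; Student's pooled
#' optionally) comparing patients with controls, then applies
#' Benjamini-Hochberg FDR across the tested family.  The default family is
#' all edges of the scheme across both hemispheres; `fdr_family =
#' "per-hemisphere"` adjusts within each hemisphere separately.
#'
#' @param fc Subjects x edges Fisher-z matrix from [extract_fc_vector()].
#' @param group Character/factor vector (`"patient"`/`"control"`) aligned
#'   with the rows of `fc`.
#' @param hemisphere Optional filter: test only edges of one hemisphere.
#' @param variant `"welch"` (default) or `"student"`.
#' @param fdr_family `"all"` (default) or `"per-hemisphere"`.
#' @param alpha Adjusted significance threshold (default 0.05).
#' @return A `cbtc_edge_stats` data frame with columns `edge`, `loop`,
#'   `hemisphere`, `t`, `p`, `p_fdr`, `direction`, `significant`.
#' @export
compare_groups <- function(fc, group, hemisphere = NULL,
                           variant = c("welch", "student"),
                           fdr_family = c("all", "per-hemisphere"),
                           alpha = 0.05) {
  variant <- match.arg(variant)
  fdr_family <- match.arg(fdr_family)
  group <- as.character(group)
  if (length(group) != nrow(fc)) stop_cbtc("group length must match fc rows")
  if (sum(group == "patient") < 2L || sum(group == "control") < 2L) {
    stop_cbtc("need at least 2 subjects per group")
  }
  if (anyNA(fc)) stop_cbtc("fc contains missing values; complete cases only")
  edges <- attr(fc, "edge_table")
  if (is.null(edges)) {
    edges <- data.frame(edge = colnames(fc), loop = NA_character_,
                        hemisphere = NA_character_, stringsAsFactors = FALSE)
  }
  if (!is.null(hemisphere)) {
    keep <- edges$hemisphere %in% hemisphere
    edges <- edges[keep, , drop = FALSE]
    fc <- fc[, keep, drop = FALSE]
  }
  pat <- fc[group == "patient", , drop = FALSE]
  ctl <- fc[group == "control", , drop = FALSE]
  res <- vapply(seq_len(ncol(fc)), function(j) {
    x <- pat[, j]
    y <- ctl[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    ht <- stats::t.test(x, y, var.equal = (variant == "student"))
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2))
  out <- data.frame(
    edge = edges$edge, loop = edges$loop, hemisphere = edges$hemisphere,
    t = res[1L, ], p = res[2L, ],
    direction = ifelse(colMeans(pat) < colMeans(ctl),
                       "patients<controls", "patients>controls"),
    stringsAsFactors = FALSE)
  if (anyNA(out$p)) {
    stop_cbtc("degenerate variance on edge '", out$edge[is.na(out$p)][1L],
              "'")
  }
  if (fdr_family == "all") {
    out$p_fdr <- bh_fdr(out$p)
  } else {
    out$p_fdr <- NA_real_
    for (h in unique(out$hemisphere)) {
      idx <- out$hemisphere == h
      out$p_fdr[idx] <- bh_fdr(out$p[idx])
    }
  }
  out$significant <- out$p_fdr < alpha
  out <- out[, c("edge", "loop", "hemisphere", "t", "p", "p_fdr",
                 "direction", "significant")]
  class(out) <- c("cbtc_edge_stats", "data.frame")
  attr(out, "variant") <- variant
  attr(out, "fdr_family") <- fdr_family
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.cbtc_edge_stats <- function(x, ...) {
  cat("Edge-wise group comparison (", attr(x, "variant"), " t-test, BH-FDR ",
      "family '", attr(x, "fdr_family"), "'): ", nrow(x), " edges, ",
      sum(x$significant), " significant at adjusted p < ",
      attr(x, "alpha"), "\n", sep = "")
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig)) print.data.frame(sig, row.names = FALSE, digits = 4)
  invisible(x)
}
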