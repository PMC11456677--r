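# Shared fixtures, built in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small but realistic cohort reused by several files.
small_cohort <- function() {
  memo("small_cohort", simulate_cohort(sim_config(
    n_patients = 10, n_controls = 10, n_timepoints = 120,
    voxels_per_subdivision = 10, seed = 101)))
}

small_fc_loops <- function() {
  memo("small_fc_loops", extract_fc_vector(small_cohort(), scheme = "loops"))
}

# Random FC-like matrix with loop edge names (pure noise features).
noise_fc <- function(n, n_edges = NULL, seed = 1) {
  edges <- loop_edge_ids()
  if (!is.null(n_edges)) edges <- edges[seq_len(n_edges)]
  set.seed(seed)
  matrix(rnorm(n * length(edges)), n,
         dimnames = list(sprintf("s%02d", seq_len(n)), edges))
}

loop_edge_ids <- function() {
  memo("loop_edge_ids", {
    e <- default_loop_manifest()$edges
    e$edge[e$loop %in% c("short", "long")]
  })
}

# Brute-force oracles (kept independent of the implementation paths).

brute_auc <- function(dv, labels) {
  pos <- dv[labels > 0]
  neg <- dv[labels < 0]
  pairs <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(pairs)
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

brute_chi2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

brute_U <- function(xs, ys) {
  sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
}
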