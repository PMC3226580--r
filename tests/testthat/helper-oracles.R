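# Independent oracles used to freeze expected values. These are written
# from the definitions (ecdf difference, explicit walks, closed forms) and
# share no code with the package internals they check.

# Signed maximum-deviation running-sum statistic, computed step by step
# from the weighted hit/miss ecdf difference. Positive tie wins.
oracle_es <- function(metrics, hit_idx, weight = 0) {
  N <- length(metrics)
  k <- length(hit_idx)
  w <- abs(metrics[hit_idx])^weight
  if (sum(w) == 0) w <- rep(1, k)
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (i %in% hit_idx) {
      acc <- acc + w[match(i, hit_idx)] / sum(w)
    } else {
      acc <- acc - 1 / (N - k)
    }
    running[i] <- acc
  }
  top <- max(running); bot <- min(running)
  if (top >= -bot) top else bot
}

# Exhaustive null over every size-k subset of an N-long ranked list.
oracle_exhaustive_null <- function(metrics, k, weight = 0) {
  apply(utils::combn(length(metrics), k), 2,
        function(idx) oracle_es(metrics, idx, weight))
}

# Closed-form two-sided power of the pooled-variance two-sample t-test.
oracle_power <- function(delta, sd, n, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tc <- qt(1 - alpha / 2, df)
  (1 - pt(tc, df, ncp)) + pt(-tc, df, ncp)
}

# A tiny ranked list with distinct metrics for enrichment tests.
toy_ranked <- function(n = 8, seed = 42) {
  set.seed(seed)
  ranked_list(sprintf("g%02d", 1:n), sort(rnorm(n, sd = 2), decreasing = TRUE))
}

# Craft an nes_matrix directly from NES values and a logical significance
# mask (significant cells get p = 0.01, the rest p = 0.5).
mock_nes <- function(nes, sig, alpha = 0.05) {
  p <- matrix(0.5, nrow(nes), ncol(nes), dimnames = dimnames(nes))
  p[sig] <- 0.01
  p[is.na(nes)] <- NA_real_
  nes_matrix(nes, p, alpha)
}

# A hand-built signed pathway_network from an edge table, for partition
# tests: nodes named, edges data.frame(from, to, sign).
mock_network <- function(nodes, edges) {
  n <- length(nodes)
  pcc <- diag(1, n); dimnames(pcc) <- list(nodes, nodes)
  pp <- matrix(1, n, n, dimnames = dimnames(pcc)); diag(pp) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    pcc[a, b] <- pcc[b, a] <- 0.9 * edges$sign[i]
    pp[a, b] <- pp[b, a] <- 1e-8
  }
  build_network(pcc, pp, r_min = 0.5, p_max = 1e-4)
}
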