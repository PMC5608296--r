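# Independent brute-force oracle for the exact Mann-Whitney test: enumerate
# every assignment of the pooled mid-ranks to the two groups and take the
# doubled smaller tail of the rank-sum. Kept deliberately naive.
brute_force_mwu <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  combs <- utils::combn(n, n1)
  w_all <- apply(combs, 2L, function(idx) sum(r[idx]))
  w_obs <- sum(r[seq_len(n1)])
  total <- ncol(combs)
  eps <- 1e-9
  p_lo <- sum(w_all <= w_obs + eps) / total
  p_hi <- sum(w_all >= w_obs - eps) / total
  list(u_stat = w_obs - n1 * (n1 + 1) / 2,
       p_two_sided = min(1, 2 * min(p_lo, p_hi)))
}

# Small, fast generator configuration for structural tests.
quick_config <- function(...) {
  array_sim_config(n_genes = 300L, frac_de = 0.1, seed = 7L, ...)
}
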