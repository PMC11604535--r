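# Shared fixtures and independent oracles used across the suite.

# Small expression matrix with explicit dimnames.
make_em <- function(values, scale = "linear",
                    genes = sprintf("g%02d", seq_len(nrow(values))),
                    samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale = scale)
}

# Wrap an arbitrary matrix as already-standardized (bypassing preprocessing)
# for direct tests of the inference layer.
make_std_em <- function(values, ...) make_em(values, scale = "standardized", ...)

# Independent normal-equations oracle: OLS coefficients of y on cbind(1, X)
# via an explicit solve of t(X)X beta = t(X)y.
oracle_ols <- function(y, X) {
  Xd <- cbind(1, X)
  as.numeric(solve(t(Xd) %*% Xd, t(Xd) %*% y))
}

# Brute-force covariation-F1 enumerator: walks the ranking explicitly,
# counting true positives at each positive's cutoff.
oracle_covariation_f1 <- function(ranked_ids, positives) {
  f1s <- c()
  for (c0 in seq_along(ranked_ids)) {
    if (!(ranked_ids[c0] %in% positives)) next
    tp <- 0
    for (i in seq_len(c0)) if (ranked_ids[i] %in% positives) tp <- tp + 1
    prec <- tp / c0
    rec <- tp / length(positives)
    f1s <- c(f1s, if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
  }
  mean(f1s)
}

# Exhaustive hypergeometric upper tail: enumerate all draws of size n from
# the universe and count those with overlap >= k.
oracle_hypergeom <- function(universe_size, set_size, n_drawn, k_overlap) {
  draws <- utils::combn(universe_size, n_drawn)
  in_set <- seq_len(set_size)  # wlog the set is the first set_size elements
  hits <- apply(draws, 2, function(d) sum(d %in% in_set) >= k_overlap)
  mean(hits)
}

# Default small synthetic cohort shared by several tests (memoized).
.small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 11L, n_genes = 600L, n_each = 50L) {
  key <- paste(seed, n_genes, n_each, sep = "_")
  if (!is.null(.small_cohort_cache[[key]])) return(.small_cohort_cache[[key]])
  cfg <- generator_config(n_genes = n_genes,
                          n_per_condition = c(healthy = n_each,
                                              moderate_infection = n_each,
                                              sepsis = n_each),
                          seed = seed)
  co <- generate_cohort(cfg)
  ctrl <- co$bundle$samples$sample_id[co$bundle$samples$condition == "healthy"]
  z <- preprocess_pipeline(co$bundle$expression, control_sample_ids = ctrl)
  lev <- standardize_levels(program_levels(z, co$w_rt, co$w_si), ctrl)
  out <- list(co = co, z = z, lev = lev, ctrl = ctrl, cfg = cfg)
  .small_cohort_cache[[key]] <- out
  out
}
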