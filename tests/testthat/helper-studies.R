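# Shared fixtures and independent oracles, all built in code.

# small clean study (no missing data unless asked)
tiny_study <- function(N = 90, M = 40, C = 2, P = 2, seed = 3,
                       missing_rate = 0.02, n_causal = 2, h2 = 0.4,
                       proportions = NULL) {
  simulate_study(sim_config(
    n_samples = N, n_snps = M, n_covariates = C, n_nodes = P,
    n_causal = n_causal, heritability = h2, missing_rate = missing_rate,
    seed = seed), proportions = proportions)
}

# independent pooled-ridge oracle: direct normal-equations solve
ridge_oracle <- function(X, y, lambda) {
  drop(solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, y)))
}

# split rows of (X, y) into P contiguous parts
split_rows <- function(X, y, P) {
  sizes <- diff(round(seq(0, nrow(X), length.out = P + 1)))
  off <- cumsum(c(0, head(sizes, -1)))
  lapply(seq_len(P), function(p) {
    idx <- seq.int(off[p] + 1L, off[p] + sizes[p])
    list(X = X[idx, , drop = FALSE], y = y[idx])
  })
}

# cache for the acceptance-scale runs (shared across test files)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_big_run <- function() {
  if (!is.null(.acceptance_cache$big)) return(.acceptance_cache$big)
  cfg <- sim_config(n_samples = 2000, n_snps = 5000, n_covariates = 3,
                    n_nodes = 3, n_causal = 50, heritability = 0.5,
                    seed = 101)
  st <- simulate_study(cfg)
  conf <- gwas_config(K = 5, R = 5, block_size = 500, seed = 101)
  fit_d <- run_ppgwas(st, conf, audit_hashes = TRUE)
  fit_p <- run_plaintext_gwas(st, conf)
  .acceptance_cache$big <- list(study = st, config = conf,
                                fit_d = fit_d, fit_p = fit_p)
  .acceptance_cache$big
}
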