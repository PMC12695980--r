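# Stacked ridge regression (REGENIE lineage), centralized plaintext path.
# Level 0: per-block ridge predictors over a grid of penalties, fitted in a
# K-fold scheme so every sample's prediction comes from models that never saw
# its fold. Level 1: a second ridge fit on the assembled prediction features,
# with the penalty chosen by cross-validated residual sum of squares. The
# polygenic-adjusted residual then drives a per-SNP 1-df chi-squared test.

#' Ridge penalty grid
#'
#' `R` heritability fractions `h_r` linearly spaced on `[0.01, 0.99]`
#' induce the Level-0 penalties `lambda_r = M (1 - h_r^2) / h_r^2` and the
#' Level-1 penalties `omega_r = (B R / M) lambda_r`.
#'
#' @param M Number of SNPs in the study.
#' @param B Number of vertical genotype blocks.
#' @param R Number of grid points (`>= 2`).
#' @return Object of class `ridge_grid` with `h`, `lambda`, `omega`, `R`,
#'   `M`, `B`.
#' @export
#' @examples
#' build_ridge_grid(M = 1000, B = 10, R = 5)$lambda[3]  # 3000
build_ridge_grid <- function(M, B, R = 5L) {
  if (!is_count(M)) stopf("M must be a positive integer")
  if (!is_count(B)) stopf("B must be a positive integer")
  if (!is_count(R, 2L)) stopf("the ridge grid needs R >= 2 penalties")
  r <- seq_len(R)
  h <- (0.01 * (R - 1) + 0.98 * (r - 1)) / (R - 1)
  lambda <- M * (1 - h^2) / h^2
  omega <- (B * R / M) * lambda
  structure(list(R = as.integer(R), h = h, lambda = lambda, omega = omega,
                 M = as.integer(M), B = as.integer(B)),
            class = "ridge_grid")
}

#' @export
print.ridge_grid <- function(x, ...) {
  cat(sprintf("<ridge grid: R=%d, M=%d, B=%d>\n", x$R, x$M, x$B))
  print(tibble(r = seq_len(x$R), h = x$h, lambda = x$lambda, omega = x$omega))
  invisible(x)
}

#' Vertical SNP blocks
#'
#' Contiguous blocks in SNP order; the last block holds the remainder.
#'
#' @param M Number of SNPs.
#' @param block_size Target SNPs per block.
#' @return Tibble with `block`, `from`, `to`, `size`.
#' @export
make_blocks <- function(M, block_size) {
  if (!is_count(block_size)) stopf("block_size must be a positive integer")
  from <- seq.int(1L, M, by = block_size)
  to <- pmin(from + block_size - 1L, M)
  tibble(block = seq_along(from), from = from, to = to,
         size = to - from + 1L)
}

#' Fold assignment shared by all nodes
#'
#' A seeded global interleave: the samples are shuffled once (by global
#' index, so the labels do not depend on how the study is partitioned across
#' nodes) and folds assigned cyclically along the shuffled order. Errors if
#' any node would end up with an empty fold.
#'
#' @param N Pooled sample count.
#' @param K Number of folds.
#' @param seed A [shared_seed()].
#' @param node_sizes Optional per-node sample counts for the coverage check.
#' @return Integer vector of fold labels in `1..K`.
#' @export
fold_assignment <- function(N, K, seed, node_sizes = NULL) {
  if (!is_count(K, 2L)) stopf("K must be an integer >= 2")
  if (N < K) stopf("cannot form %d folds from %d samples", K, N)
  ord <- with_stream(derive_seed(as_shared_seed(seed), "level0", "folds"),
                     sample(N))
  folds <- integer(N)
  folds[ord] <- rep_len(seq_len(K), N)
  if (!is.null(node_sizes)) {
    off <- cumsum(c(0L, head(node_sizes, -1L)))
    for (p in seq_along(node_sizes)) {
      idx <- seq.int(off[p] + 1L, off[p] + node_sizes[p])
      if (length(unique(folds[idx])) < K)
        stopf("node %d has an empty fold; increase node size or reduce K", p)
    }
  }
  folds
}

# Closed-form ridge solves for one (fold, block): eigendecompose the training
# Gram once, then sweep the penalty grid.
ridge_solve_grid <- function(Xtr, ytr, lambdas) {
  G <- crossprod(Xtr)
  cvec <- crossprod(Xtr, ytr)
  eg <- eigen(G, symmetric = TRUE)
  Uc <- crossprod(eg$vectors, cvec)
  sapply(lambdas, function(l) drop(eg$vectors %*% (Uc / (eg$values + l))))
}

#' Level-0 out-of-fold ridge predictions
#'
#' For every (fold `k`, block `b`, penalty `r`): ridge coefficients from the
#' closed-form solve on all folds except `k`, predictions on fold `k`. The
#' predictions are assembled into the `N x (B R)` feature matrix `W` with
#' column order block-major (`(b-1) R + r`), so each row of `W` comes from
#' models that never saw that row's fold.
#'
#' @param Xt Projected, standardized genotype matrix.
#' @param yt Projected, standardized phenotype.
#' @param blocks Block table from [make_blocks()].
#' @param folds Fold labels from [fold_assignment()].
#' @param grid A [build_ridge_grid()].
#' @return Object of class `level0_predictions`: `W`, `blocks`, `grid`,
#'   `folds`.
#' @export
level0_fit_predict <- function(Xt, yt, blocks, folds, grid) {
  N <- nrow(Xt); K <- max(folds); B <- nrow(blocks); R <- grid$R
  if (any(tabulate(folds, K) == 0L)) stopf("fold with 0 samples")
  W <- matrix(0, N, B * R)
  for (b in seq_len(B)) {
    idx <- seq.int(blocks$from[b], blocks$to[b])
    Xb <- Xt[, idx, drop = FALSE]
    for (k in seq_len(K)) {
      te <- folds == k
      betas <- ridge_solve_grid(Xb[!te, , drop = FALSE], yt[!te], grid$lambda)
      W[te, (b - 1L) * R + seq_len(R)] <- Xb[te, , drop = FALSE] %*% betas
    }
  }
  structure(list(W = W, blocks = blocks, grid = grid, folds = folds),
            class = "level0_predictions")
}

#' Level-1 cross-validated ridge fit
#'
#' Per fold `k` and penalty `omega_r`, the closed-form ridge fit of the
#' phenotype on the out-of-fold feature matrix `W_{k-1}`; the optimal grid
#' index `r*` minimizes the summed out-of-fold residual sum of squares (ties
#' toward the smallest `r`); the global predictor stitches the per-fold
#' predictions `W_k eta_{(k-1, r*)}` together.
#'
#' @param l0 A [level0_fit_predict()] result (or a bare `W` matrix plus
#'   `folds`/`grid` arguments).
#' @param yt Projected, standardized phenotype.
#' @param folds,grid Used when `l0` is a bare matrix.
#' @return Object of class `level1_fit`: `eta` (`BR x K` matrix at `r*`),
#'   `r_star`, `yhat`, `rss` (`K x R`), `grid`.
#' @export
level1_fit <- function(l0, yt, folds = NULL, grid = NULL) {
  if (inherits(l0, "level0_predictions")) {
    W <- l0$W; folds <- l0$folds; grid <- l0$grid
  } else W <- l0
  K <- max(folds); R <- grid$R; BR <- ncol(W)
  rss <- matrix(0, K, R)
  eta_all <- array(0, c(BR, K, R))
  for (k in seq_len(K)) {
    te <- folds == k
    A <- crossprod(W[!te, , drop = FALSE])
    rhs <- crossprod(W[!te, , drop = FALSE], yt[!te])
    eg <- eigen(A, symmetric = TRUE)
    Ur <- crossprod(eg$vectors, rhs)
    for (r in seq_len(R)) {
      eta <- drop(eg$vectors %*% (Ur / (eg$values + grid$omega[r])))
      eta_all[, k, r] <- eta
      rss[k, r] <- sum((yt[te] - W[te, , drop = FALSE] %*% eta)^2)
    }
  }
  r_star <- which.min(colSums(rss))   # ties break toward the smallest r
  yhat <- numeric(length(yt))
  for (k in seq_len(K)) {
    te <- folds == k
    yhat[te] <- W[te, , drop = FALSE] %*% eta_all[, k, r_star]
  }
  structure(list(eta = eta_all[, , r_star, drop = TRUE], r_star = r_star,
                 yhat = yhat, rss = rss, grid = grid),
            class = "level1_fit")
}

#' Single-SNP chi-squared association test
#'
#' For each projected, standardized test SNP `x~`:
#' `chi2 = (x~' (y~ - y^))^2 / (sigma2_e * x~'x~)` with
#' `sigma2_e = ||y~ - y^||^2 / (N - C)`, 1 degree of freedom, two-sided
#' p-values from the chi-squared survival function.
#'
#' @param xt Matrix of projected standardized test SNPs (columns) — or a
#'   single vector.
#' @param yt,yhat Projected phenotype and stacked-ridge predictor.
#' @param C Columns of the intercept-augmented covariate matrix.
#' @return Tibble with `chisq`, `p`, and attribute `sigma2`.
#' @export
#' @examples
#' chi2_test(cbind(c(1, -1, 1, -1)), c(1, -1, 0, 0), rep(0, 4), C = 1)$chisq  # 1.5
chi2_test <- function(xt, yt, yhat, C) {
  if (is.null(dim(xt))) xt <- cbind(xt)
  N <- length(yt)
  resid <- yt - yhat
  sigma2 <- sum(resid^2) / (N - C)
  xx <- colSums(xt^2)
  if (any(xx == 0)) stopf("test SNP with zero norm (x~'x~ = 0)")
  num <- drop(crossprod(xt, resid))^2
  chisq <- num / (sigma2 * xx)
  out <- tibble(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
  attr(out, "sigma2") <- sigma2
  out
}

#' GWAS engine configuration
#'
#' Tunables shared by the plaintext engine and the distributed protocol.
#'
#' @param K Number of cross-validation folds.
#' @param R Ridge-grid size.
#' @param block_size SNPs per Level-0 block.
#' @param qc [qc_thresholds()].
#' @param sig_threshold Genome-wide significance threshold on p.
#' @param seed Shared seed (integer or [shared_seed()]).
#' @param admm_ell ADMM penalty (`NULL` = automatic `n_train / P` heuristic).
#' @param admm_relax ADMM over-relaxation factor.
#' @param admm_max_iter,admm_tol ADMM iteration cap and relative residual
#'   tolerance.
#' @param cg_tol Conjugate-gradient residual tolerance (Level 1).
#' @param shuffle_snps Shuffle SNP order before the server computes the
#'   association statistics (optional hiding of SNP identity; off by
#'   default).
#' @param identity_encoding Degenerate test-only mode: all pads 0 and
#'   identity obfuscation. Refused by [run_ppgwas()] unless
#'   `allow_insecure = TRUE`.
#' @param allow_insecure Permit `identity_encoding` (test harnesses only).
#' @return List of class `gwas_config`.
#' @export
gwas_config <- function(K = 5L, R = 5L, block_size = 1000L,
                        qc = qc_thresholds(), sig_threshold = 5e-8,
                        seed = 1L, admm_ell = NULL, admm_relax = 1.8,
                        admm_max_iter = 1500L, admm_tol = 1e-12,
                        cg_tol = 1e-12, shuffle_snps = FALSE,
                        identity_encoding = FALSE, allow_insecure = FALSE) {
  if (!is_count(K, 2L)) stopf("K must be >= 2")
  if (!is_count(R, 2L)) stopf("R must be >= 2")
  if (!is_count(block_size)) stopf("block_size must be a positive integer")
  structure(list(K = as.integer(K), R = as.integer(R),
                 block_size = as.integer(block_size), qc = qc,
                 sig_threshold = sig_threshold, seed = as_shared_seed(seed),
                 admm_ell = admm_ell, admm_relax = admm_relax,
                 admm_max_iter = as.integer(admm_max_iter),
                 admm_tol = admm_tol, cg_tol = cg_tol,
                 shuffle_snps = isTRUE(shuffle_snps),
                 identity_encoding = isTRUE(identity_encoding),
                 allow_insecure = isTRUE(allow_insecure)),
            class = "gwas_config")
}

pool_study <- function(study) {
  if (!is.null(study$X)) return(study)
  list(X = do.call(rbind, lapply(study$nodes, `[[`, "X")),
       Z = do.call(rbind, lapply(study$nodes, `[[`, "Z")),
       y = unlist(lapply(study$nodes, `[[`, "y")),
       snp_info = study$snp_info)
}

#' Centralized plaintext stacked-ridge GWAS
#'
#' The pooled-data oracle: QC on pooled counts, count-derived
#' standardization, covariate projection, Level-0/Level-1 stacked ridge, and
#' the per-SNP chi-squared test. Deterministic given `(study, config)`.
#'
#' @param study A [simulate_study()] object, or a list with `X`, `Z`, `y`
#'   (and optionally `snp_info`).
#' @param config A [gwas_config()].
#' @return Object of class `gwas_fit` — see [tidy.gwas_fit()],
#'   [glance.gwas_fit()], [autoplot.gwas_fit()].
#' @export
#' @examples
#' st <- simulate_study(sim_config(n_samples = 120, n_snps = 60, n_causal = 3,
#'                                 heritability = 0.4, missing_rate = 0, seed = 2))
#' fit <- run_plaintext_gwas(st, gwas_config(K = 3, R = 3, block_size = 20))
#' head(tidy(fit))
run_plaintext_gwas <- function(study, config = gwas_config()) {
  pooled <- pool_study(study)
  X <- pooled$X; Z <- pooled$Z; y <- pooled$y
  N <- nrow(X)
  snp_info <- pooled$snp_info %||%
    tibble(snp_id = sprintf("snp%06d", seq_len(ncol(X))),
           chrom = 1L, pos = seq_len(ncol(X)))

  counts <- local_counts(X)
  qc <- apply_filters(counts, config$qc, snp_id = snp_info$snp_id)
  keep <- which(qc$pass)
  if (!length(keep)) stopf("QC removed every SNP: empty study")
  stats <- standardization_from_counts(counts[keep, , drop = FALSE])
  pr <- project_covariates_plaintext(X[, keep, drop = FALSE], Z, y, stats)

  M_kept <- length(keep)
  blocks <- make_blocks(M_kept, config$block_size)
  grid <- build_ridge_grid(M_kept, nrow(blocks), config$R)
  folds <- fold_assignment(N, config$K, config$seed)
  l0 <- level0_fit_predict(pr$Xt, pr$yt, blocks, folds, grid)
  l1 <- level1_fit(l0, pr$yt)
  assoc <- chi2_test(pr$Xt, pr$yt, l1$yhat, pr$C)

  results <- dplyr::left_join(
    dplyr::bind_cols(snp_info[, intersect(c("snp_id", "chrom", "pos"),
                                          names(snp_info))],
                     qc[, c("missing_rate", "maf", "hwe_chisq", "pass")]),
    tibble(snp_id = snp_info$snp_id[keep], chisq = assoc$chisq, p = assoc$p),
    by = "snp_id")
  structure(list(results = results, qc = qc, grid = grid, folds = folds,
                 r_star = l1$r_star, sigma2 = attr(assoc, "sigma2"),
                 rss = l1$rss, config = config, n_samples = N,
                 n_retained = M_kept, C = pr$C, engine = "plaintext"),
            class = "gwas_fit")
}

#' Write association results as TSV
#'
#' Deterministic column order: snp_id, chrom, pos, missing_rate, maf,
#' hwe_chisq, pass, chisq, p.
#'
#' @param fit A `gwas_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_association <- function(fit, path) {
  df <- as.data.frame(fit$results)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
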