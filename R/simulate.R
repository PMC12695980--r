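# Synthetic quantitative-trait studies: Balding-Nichols population structure,
# haplotype-sharing family relatedness, polygenic phenotypes with a target
# heritability, and horizontal partitioning across computational nodes.

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-study generator. The
#' defaults reproduce the statistical structure the pipeline assumes:
#' population structure (Fst-like differentiation) 0.1 and a fraction 0.25 of
#' samples in related pairs, with a 2% genotype missing rate so QC filters
#' are exercised.
#'
#' @param n_samples Total sample count `N`.
#' @param n_snps SNP count `M`.
#' @param n_covariates Number of covariates `C` (intercept not included).
#' @param n_nodes Number of computational nodes `P`.
#' @param n_subpops Number of subpopulations for the Balding-Nichols model.
#' @param fst Population-structure parameter in `[0, 1)`.
#' @param relatedness Fraction of samples belonging to related pairs, in
#'   `[0, 1)`.
#' @param n_causal Number of causal SNPs.
#' @param heritability Proportion of phenotypic variance explained by the
#'   causal genotypic effects, in `[0, 1]`.
#' @param missing_rate Genotype missingness rate in `[0, 1)`.
#' @param seed Integer seed; all generation is reproducible from
#'   `(config, seed)`.
#' @return A validated object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 200, n_snps = 100, n_causal = 5,
#'                   heritability = 0.3, seed = 1)
sim_config <- function(n_samples, n_snps, n_covariates = 0L, n_nodes = 1L,
                       n_subpops = 2L, fst = 0.1, relatedness = 0.25,
                       n_causal = 0L, heritability = 0, missing_rate = 0.02,
                       seed = 1L) {
  if (!is_count(n_samples)) stopf("n_samples must be a positive integer")
  if (!is_count(n_snps)) stopf("n_snps must be a positive integer")
  if (!is_count(n_covariates, 0L)) stopf("n_covariates must be >= 0")
  if (!is_count(n_nodes)) stopf("n_nodes must be a positive integer")
  if (!is_count(n_subpops)) stopf("n_subpops must be a positive integer")
  if (!is_prob(fst, closed_upper = FALSE)) stopf("fst must lie in [0, 1)")
  if (!is_prob(relatedness, closed_upper = FALSE))
    stopf("relatedness must lie in [0, 1)")
  if (!is_count(n_causal, 0L) || n_causal > n_snps)
    stopf("n_causal must be an integer in [0, n_snps]")
  if (!is_prob(heritability)) stopf("heritability must lie in [0, 1]")
  if (heritability > 0 && n_causal == 0L)
    stopf("heritability > 0 requires n_causal > 0")
  if (!is_prob(missing_rate, closed_upper = FALSE))
    stopf("missing_rate must lie in [0, 1)")
  if (n_samples < n_nodes) stopf("every node must receive at least one sample")
  structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_covariates = as.integer(n_covariates), n_nodes = as.integer(n_nodes),
    n_subpops = as.integer(n_subpops), fst = fst, relatedness = relatedness,
    n_causal = as.integer(n_causal), heritability = heritability,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate dosage genotypes with population structure and relatedness
#'
#' Per SNP, an ancestral allele frequency is drawn uniformly on
#' `[0.05, 0.95]`; subpopulation frequencies follow a Balding-Nichols
#' (beta) model with differentiation parameter `fst`; dosages are
#' `Binomial(2, p)` draws. A fraction `relatedness` of samples form pairs
#' that share one parental haplotype draw. Missing entries (`NA`) are
#' introduced at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return List with `X` (`N x M` integer dosage matrix, `NA` for missing),
#'   `snp_info` (tibble: snp_id, chrom, pos, ancestral_freq), `subpop`
#'   (per-sample subpopulation label) and `subpop_freqs` (the realized
#'   `n_subpops x M` allele-frequency draws, useful for checking the
#'   differentiation model).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_samples; M <- config$n_snps; S <- config$n_subpops
  fst <- config$fst
  ss <- shared_seed(config$seed)

  p_anc <- with_stream(derive_seed(ss, "genotypes", "ancestral"),
                       runif(M, 0.05, 0.95))
  # subpopulation allele frequencies: Balding-Nichols beta draws
  p_sub <- with_stream(derive_seed(ss, "genotypes", "subpop"), {
    if (fst == 0 || S == 1L) {
      matrix(rep(p_anc, each = S), S, M)
    } else {
      a <- p_anc * (1 - fst) / fst
      b <- (1 - p_anc) * (1 - fst) / fst
      matrix(stats::rbeta(S * M, rep(a, each = S), rep(b, each = S)), S, M)
    }
  })
  subpop <- rep_len(seq_len(S), N)

  X <- with_stream(derive_seed(ss, "genotypes", "relatedness"), {
    # two parental haplotype draws per sample; related pairs share the first
    n_rel_pairs <- floor(config$relatedness * N / 2)
    pair_first <- if (n_rel_pairs > 0) seq(1L, by = 2L, length.out = n_rel_pairs)
                  else integer(0)
    P1 <- matrix(0L, N, M); P2 <- matrix(0L, N, M)
    for (s in seq_len(S)) {
      rows <- which(subpop == s)
      if (!length(rows)) next
      ps <- p_sub[s, ]
      P1[rows, ] <- matrix(rbinom(length(rows) * M, 1L, rep(ps, each = length(rows))),
                           length(rows), M)
      P2[rows, ] <- matrix(rbinom(length(rows) * M, 1L, rep(ps, each = length(rows))),
                           length(rows), M)
    }
    # relatedness: second member of each pair reuses the first member's P1
    for (i in pair_first) P1[i + 1L, ] <- P1[i, ]
    P1 + P2
  })

  if (config$missing_rate > 0) {
    X <- with_stream(derive_seed(ss, "genotypes", "missing"), {
      miss <- runif(length(X)) < config$missing_rate
      X[miss] <- NA_integer_
      X
    })
  }
  snp_info <- tibble(
    snp_id = sprintf("snp%06d", seq_len(M)),
    chrom = 1L + ((seq_len(M) - 1L) %/% max(1L, ceiling(M / 22))),
    pos = 1000L * seq_len(M),
    ancestral_freq = p_anc
  )
  list(X = X, snp_info = snp_info, subpop = subpop, subpop_freqs = p_sub)
}

#' Simulate covariates
#'
#' Standard-normal covariate columns (seeded); a thin helper so studies and
#' tests share one construction.
#' @param config A [sim_config()].
#' @return `N x C` matrix (0 columns when `n_covariates = 0`).
#' @export
simulate_covariates <- function(config) {
  N <- config$n_samples; C <- config$n_covariates
  if (C == 0L) return(matrix(numeric(0), N, 0L))
  with_stream(derive_seed(shared_seed(config$seed), "covariates"),
              matrix(rnorm(N * C), N, C,
                     dimnames = list(NULL, sprintf("cov%d", seq_len(C)))))
}

#' Simulate a quantitative phenotype over given genotypes
#'
#' Builds `y = Z alpha + X beta + e` with `beta` non-zero only on a seeded
#' causal set and the genetic component rescaled so that the in-sample
#' variance ratio `Var(X beta) / Var(y)` equals `heritability` exactly.
#' Genotypes are mean-imputed and standardized internally before effects are
#' applied; `e` is Gaussian.
#'
#' @param X `N x M` dosage matrix (may contain `NA`).
#' @param Z `N x C` covariate matrix (may have zero columns).
#' @param config A [sim_config()].
#' @param alpha Optional length-`C` covariate effect vector (default zeros).
#' @return List with `y`, `beta` (length `M`, zeros off the causal set),
#'   `causal` (indices), `alpha`, and the realized `var_ratio`.
#' @export
simulate_phenotype <- function(X, Z, config, alpha = NULL) {
  stopifnot(inherits(config, "sim_config"))
  N <- nrow(X); M <- ncol(X)
  h2 <- config$heritability
  if (h2 >= 1 && config$n_causal == 0L)
    stopf("heritability 1 with no causal SNPs is not a valid model")
  C <- ncol(Z)
  if (is.null(alpha)) alpha <- numeric(C)
  if (length(alpha) != C) stopf("alpha must have length ncol(Z) = %d", C)
  ss <- shared_seed(config$seed)

  causal <- if (config$n_causal > 0L)
    with_stream(derive_seed(ss, "phenotype", "effects"),
                sort(sample(M, config$n_causal))) else integer(0)
  beta <- numeric(M)
  zpart <- if (C > 0L) drop(Z %*% alpha) else numeric(N)
  v_z <- if (C > 0L) var_pop(zpart) else 0

  g <- numeric(N)
  if (length(causal) && h2 > 0) {
    Xc <- X[, causal, drop = FALSE]
    mu <- colMeans(Xc, na.rm = TRUE)
    for (j in seq_along(causal)) Xc[is.na(Xc[, j]), j] <- mu[j]
    sdv <- apply(Xc, 2L, function(v) sqrt(var_pop(v)))
    if (any(sdv == 0)) sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xc, 2L, mu), 2L, sdv, `/`)
    b0 <- with_stream(derive_seed(ss, "phenotype", "effects", "noise"),
                      rnorm(length(causal)))
    g0 <- drop(Xs %*% b0)
    v0 <- var_pop(g0)
    if (v0 == 0) stopf("degenerate causal genotypes (zero-variance polygenic score)")
    # total variance target T: genetic h2*T, noise T*(1-h2) - v_z >= 0
    T_ <- max(1, if (h2 < 1) v_z / (1 - h2) * 1.25 else v_z + 1)
    scl <- sqrt(h2 * T_ / v0)
    g <- g0 * scl
    beta[causal] <- b0 * scl / sdv  # on the dosage scale
    v_e <- T_ * (1 - h2) - v_z
  } else {
    T_ <- max(1, if (h2 < 1) v_z / (1 - max(h2, 0)) * 1.25 else v_z + 1)
    v_e <- T_ - v_z
  }
  if (v_e < 0) stopf("covariate variance too large for requested heritability")
  e <- with_stream(derive_seed(ss, "phenotype", "noise"),
                   rnorm(N, sd = sqrt(v_e)))
  y <- zpart + g + e
  list(y = y, beta = beta, causal = causal, alpha = alpha,
       var_ratio = if (var_pop(y) > 0) var_pop(g) / var_pop(y) else 0)
}

var_pop <- function(x) mean((x - mean(x))^2)

#' Partition a pooled study across computational nodes
#'
#' Contiguous row slices, with each node recording its global sample offset
#' (the number of samples onboarded before it) — the quantity the protocol's
#' global obfuscation-matrix column slicing relies on.
#'
#' @param study A pooled study: list with `X`, `Z`, `y` (and optionally
#'   `snp_info`, `truth`).
#' @param n_nodes Number of nodes `P`.
#' @param proportions Optional length-`P` positive weights summing to 1;
#'   default equal split.
#' @return The study with a `nodes` element: per node `X`, `Z`, `y`,
#'   `offset`, `n`.
#' @export
#' @examples
#' st <- list(X = matrix(0L, 10, 2), Z = matrix(0, 10, 0), y = rnorm(10))
#' sapply(partition_across_nodes(st, 2)$nodes, `[[`, "n")
partition_across_nodes <- function(study, n_nodes, proportions = NULL) {
  N <- nrow(study$X)
  if (!is_count(n_nodes)) stopf("n_nodes must be a positive integer")
  if (is.null(proportions)) proportions <- rep(1 / n_nodes, n_nodes)
  if (length(proportions) != n_nodes)
    stopf("proportions must have length n_nodes")
  if (abs(sum(proportions) - 1) > 1e-8)
    stopf("proportions must sum to 1")
  sizes <- diff(round(cumsum(c(0, proportions)) * N))
  if (any(sizes < 1))
    stopf("partition assigns zero samples to a node; adjust proportions")
  offsets <- cumsum(c(0L, head(sizes, -1L)))
  nodes <- lapply(seq_len(n_nodes), function(p) {
    idx <- seq.int(offsets[p] + 1L, offsets[p] + sizes[p])
    list(X = study$X[idx, , drop = FALSE],
         Z = study$Z[idx, , drop = FALSE],
         y = study$y[idx],
         offset = as.integer(offsets[p]), n = as.integer(sizes[p]))
  })
  study$nodes <- nodes
  study$node_sizes <- as.integer(sizes)
  study
}

#' Simulate a complete partitioned study
#'
#' Genotypes, covariates, phenotype and truth record, pooled and partitioned.
#'
#' @param config A [sim_config()].
#' @param alpha Optional covariate effects (see [simulate_phenotype()]).
#' @param proportions Optional node proportions (see
#'   [partition_across_nodes()]).
#' @return An object of class `sim_study`: `X`, `Z`, `y`, `snp_info`,
#'   `truth` (tibble: snp_id, is_causal, beta), `subpop`, `config`, `nodes`.
#' @export
#' @examples
#' st <- simulate_study(sim_config(n_samples = 60, n_snps = 30, n_nodes = 2,
#'                                 n_causal = 3, heritability = 0.4, seed = 7))
#' names(st$nodes[[1]])
simulate_study <- function(config, alpha = NULL, proportions = NULL) {
  g <- simulate_genotypes(config)
  Z <- simulate_covariates(config)
  ph <- simulate_phenotype(g$X, Z, config, alpha = alpha)
  study <- list(X = g$X, Z = Z, y = ph$y, snp_info = g$snp_info,
                subpop = g$subpop,
                truth = tibble(snp_id = g$snp_info$snp_id,
                               is_causal = seq_len(config$n_snps) %in% ph$causal,
                               beta = ph$beta),
                alpha = ph$alpha, var_ratio = ph$var_ratio, config = config)
  study <- partition_across_nodes(study, config$n_nodes, proportions)
  class(study) <- "sim_study"
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sim_study: N=%d samples, M=%d SNPs, C=%d covariates, P=%d nodes>\n",
    cfg$n_samples, cfg$n_snps, cfg$n_covariates, cfg$n_nodes))
  cat(sprintf("  fst=%.3g, relatedness=%.3g, causal=%d, heritability=%.3g\n",
              cfg$fst, cfg$relatedness, cfg$n_causal, cfg$heritability))
  invisible(x)
}
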