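# privgwas

Privacy-preserving multi-site genome-wide association studies for
quantitative traits, in R.

## The problem

Multi-cohort GWAS have more power than any single cohort, but genotype and
phenotype data usually cannot leave the institutions that hold them.
`privgwas` lets `P` cohorts ("nodes"), each holding a horizontal slice
`(X_p, Z_p, y_p)` of a pooled study, run a *joint* association analysis with
the help of one untrusted coordinating server: the server only ever sees
randomized-encoded payloads (additively masked count tables, matrices
obfuscated on both sides by secret orthonormal maps with padded dimensions),
yet the final per-SNP statistics are algebraically equal to what a
centralized analysis of the pooled data would produce. The package is aimed
at statistical geneticists and methods researchers who want a working,
testable reference implementation of this protocol class — including a
plaintext engine that doubles as the correctness oracle.

## The method

Associations are tested under the whole-genome regression view of the
linear mixed model (the REGENIE lineage). After quality control and
projection of standardized genotypes and phenotype onto the null space of
the intercept-augmented covariates `Z1 = [Z | 1]`:

1. **Level 0** — the genotype matrix is cut into `B` vertical blocks; for a
   grid of `R` ridge penalties `lambda_r = M (1 - h_r^2) / h_r^2` (with
   `h_r` linearly spaced on `[0.01, 0.99]`), each (block, penalty) pair
   yields cross-validated out-of-fold ridge predictions, assembled into a
   feature matrix `W` (`N x BR`).
2. **Level 1** — a second cross-validated ridge fit of `y~` on `W` with
   penalties `omega_r = (BR/M) lambda_r`; the grid index `r*` minimizes the
   out-of-fold RSS and defines the polygenic predictor `y^`.
3. **Single-SNP test** — for each SNP,
   `chi2 = (x~' (y~ - y^))^2 / (sigma2_e x~'x~)` with
   `sigma2_e = ||y~ - y^||^2 / (N - C - 1)`, one degree of freedom,
   two-sided p-values, conventional genome-wide threshold `p < 5e-8`.

Distributed execution replaces each stage with a randomized encoding:
masked sums for QC counts and phenotype moments, two-sided orthonormal
obfuscation for the covariate projection, consensus ADMM on encoded
payloads for Level 0, server-side conjugate gradients for Level 1, and an
encoded one-shot exchange for the per-SNP statistics. A transcript of every
server-visible message supports a mechanical privacy audit (closed payload
catalogue, no unpadded private dimensions, no raw data rows).

## Worked example

```r
library(privgwas)

# a partitioned synthetic study: 600 samples, 600 SNPs, 2 covariates,
# population structure 0.1, relatedness 0.25, 10 causal SNPs, h2 = 0.4
study <- simulate_study(sim_config(
  n_samples = 600, n_snps = 600, n_covariates = 2, n_nodes = 3,
  n_causal = 10, heritability = 0.4, seed = 202))

conf <- gwas_config(K = 5, R = 5, block_size = 150, seed = 202)

fit  <- run_ppgwas(study, conf)          # distributed, 3 nodes + server
fit
#> <distributed privacy-preserving stacked-ridge GWAS fit>
#>   N = 600 samples, 533/600 SNPs retained by QC
#>   K = 5 folds, R = 5 penalties, B = 4 blocks; selected r* = 3 (h = 0.500)
#>   residual variance sigma2_e = 0.8784 (df = N - C = 597)
#>   2 SNP(s) below the genome-wide threshold p < 5e-08
```

`533/600 SNPs retained` is the QC outcome (missing rate <= 0.1, MAF > 0.05,
Hardy-Weinberg chi-squared <= 23.928); `r* = 3` says the cross-validated
Level-1 selection picked the middle of the penalty grid (`h = 0.5`, i.e. a
polygenic signal explaining about half the variance, matching the simulated
heritability of 0.4); `sigma2_e` is the residual variance of the
polygenic-adjusted phenotype; and 2 SNPs clear genome-wide significance.

```r
oracle <- run_plaintext_gwas(study, conf)  # centralized, pooled plaintext
log10p_r2(fit, oracle)                     # agreement of -log10(p)
#> [1] 1
max(abs(tidy(fit)$chisq - tidy(oracle)$chisq), na.rm = TRUE)
#> [1] 8.466117e-12

audit_transcript(fit)                      # mechanical privacy check
#> <transcript audit: 180 server-visible messages — clean>

head(tidy(fit), 3)                         # per-SNP tibble
#> # A tibble: 3 x 9
#>   snp_id    chrom   pos missing_rate    maf hwe_chisq pass  chisq      p
#>   <chr>     <dbl> <int>        <dbl>  <dbl>     <dbl> <lgl> <dbl>  <dbl>
#> 1 snp000001     1  1000       0.0167 0.263    0.0234  TRUE  0.469 0.493
#> 2 snp000002     1  2000       0.0233 0.0572   0.00423 TRUE  0.108 0.742
#> 3 snp000003     1  3000       0.0183 0.129    0.00504 TRUE  4.95  0.0261
```

`glance(fit)` gives a one-row summary, `autoplot(fit)` a Manhattan plot and
`plot_qq(fit)` a QQ plot. A command-line interface covers the same ground
(`simulate`, `qc`, `run-plaintext`, `run-local`, `run-server`/`run-node`
over TCP, `verify`); see `exec/privgwas --help`.

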