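test_that("configurations are validated", {
  expect_error(sim_config(100, 50, fst = 1), "fst")
  expect_error(sim_config(100, 50, fst = -0.1), "fst")
  expect_error(sim_config(100, 50, relatedness = 1.2), "relatedness")
  expect_error(sim_config(100, 50, n_causal = 60), "n_causal")
  expect_error(sim_config(100, 50, heritability = 1, n_causal = 0),
               "n_causal")
  expect_error(sim_config(3, 50, n_nodes = 5), "at least one sample")
  expect_s3_class(sim_config(100, 50), "sim_config")
})

test_that("genotypes live in {0,1,2,NA} with the configured missing rate", {
  cfg <- sim_config(400, 300, missing_rate = 0.05, seed = 21)
  g <- simulate_genotypes(cfg)
  vals <- g$X[!is.na(g$X)]
  expect_true(all(vals %in% 0:2))
  n <- length(g$X)
  miss <- mean(is.na(g$X))
  expect_lt(abs(miss - 0.05), 4 * sqrt(0.05 * 0.95 / n))
})

test_that("generation is byte-identical under a repeated seed", {
  cfg <- sim_config(60, 40, n_covariates = 2, n_causal = 3,
                    heritability = 0.3, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$X, s2$X)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$Z, s2$Z)
  expect_identical(s1$truth, s2$truth)
})

test_that("without structure, allele frequencies track the ancestral draw", {
  cfg <- sim_config(1000, 400, n_subpops = 1, fst = 0, relatedness = 0,
                    missing_rate = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  phat <- colMeans(g$X) / 2
  se <- sqrt(g$snp_info$ancestral_freq * (1 - g$snp_info$ancestral_freq) /
               (2 * 1000))
  dev <- abs(phat - g$snp_info$ancestral_freq) / se
  expect_gt(mean(dev <= 4), 0.99)
})

test_that("between-subpopulation frequency variance matches the Balding-Nichols model", {
  fst <- 0.1
  cfg <- sim_config(100, 5000, n_subpops = 2, fst = fst, relatedness = 0,
                    missing_rate = 0, seed = 41)
  g <- simulate_genotypes(cfg)
  # realized mean between-subpop variance (sample variance of 2 draws)
  realized <- mean((g$subpop_freqs[1, ] - g$subpop_freqs[2, ])^2 / 2)
  # Monte-Carlo oracle over 1e5 frequency draws from the same model
  set.seed(1)
  p <- runif(1e5, 0.05, 0.95)
  a <- p * (1 - fst) / fst; b <- (1 - p) * (1 - fst) / fst
  x1 <- rbeta(1e5, a, b); x2 <- rbeta(1e5, a, b)
  oracle <- mean((x1 - x2)^2 / 2)
  # the oracle is itself E[fst * p(1-p)] = fst * 0.1825 for p ~ U(0.05, 0.95)
  expect_lt(abs(oracle - fst * 0.1825) / (fst * 0.1825), 0.05)
  expect_lt(abs(realized - oracle) / oracle, 0.15)
})

test_that("relatedness induces the haplotype-sharing correlation in pairs", {
  cfg <- sim_config(1000, 400, n_subpops = 1, fst = 0, relatedness = 0.5,
                    missing_rate = 0, seed = 51)
  g <- simulate_genotypes(cfg)
  # center per SNP first: shared allele-frequency profiles otherwise induce
  # across-SNP correlation between any two individuals
  Xc <- scale(g$X, center = TRUE, scale = FALSE)
  # first 250 pairs share one parental haplotype -> dosage correlation ~ 0.5
  r_pair <- mean(vapply(seq(1, 499, by = 2), function(i)
    cor(Xc[i, ], Xc[i + 1, ]), numeric(1)))
  r_unrel <- mean(vapply(seq(501, 999, by = 2), function(i)
    cor(Xc[i, ], Xc[i + 1, ]), numeric(1)))
  expect_gt(r_pair, 0.4)
  expect_lt(abs(r_unrel), 0.1)
})

test_that("null phenotypes are independent of every SNP", {
  cfg <- sim_config(800, 1000, heritability = 0, n_causal = 0,
                    missing_rate = 0, seed = 61)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g$X, matrix(numeric(0), 800, 0), cfg)
  Xs <- scale(g$X)
  yc <- ph$y - mean(ph$y)
  r <- drop(crossprod(Xs, yc)) / sqrt(colSums(Xs^2) * sum(yc^2))
  tstat <- r * sqrt((800 - 2) / (1 - r^2))
  expect_true(all(abs(tstat) < 4))
  expect_true(all(ph$beta == 0))
})

test_that("the genetic variance fraction hits the target heritability", {
  cfg <- sim_config(2000, 500, n_causal = 50, heritability = 0.5,
                    missing_rate = 0, seed = 71)
  st <- simulate_study(cfg)
  expect_lt(abs(st$var_ratio - 0.5), 0.05)
})

test_that("covariate effects are recovered by least squares", {
  cfg <- sim_config(500, 200, n_covariates = 2, n_causal = 5,
                    heritability = 0.3, missing_rate = 0, seed = 81)
  g <- simulate_genotypes(cfg)
  Z <- simulate_covariates(cfg)
  ph <- simulate_phenotype(g$X, Z, cfg, alpha = c(1, -1))
  fit <- lm(ph$y ~ Z)
  est <- coef(summary(fit))[2:3, ]
  expect_true(all(abs(est[, "Estimate"] - c(1, -1)) < 2 * est[, "Std. Error"]))
})

test_that("partitioning gives contiguous slices that reassemble exactly", {
  st <- tiny_study(N = 1000, M = 20, P = 1, seed = 91, missing_rate = 0)
  # identity
  p1 <- partition_across_nodes(st, 1)
  expect_identical(p1$nodes[[1]]$X, st$X)
  # explicit proportions
  p3 <- partition_across_nodes(st, 3, proportions = c(0.5, 0.3, 0.2))
  expect_equal(vapply(p3$nodes, `[[`, 0L, "n"), c(500L, 300L, 200L))
  expect_equal(vapply(p3$nodes, `[[`, 0L, "offset"), c(0L, 500L, 800L))
  # round trip
  expect_identical(do.call(rbind, lapply(p3$nodes, `[[`, "X")), st$X)
  expect_identical(unlist(lapply(p3$nodes, `[[`, "y")), st$y)
  # a zero-sample node is rejected
  expect_error(partition_across_nodes(st, 3, proportions = c(0.999, 0.0005, 0.0005)),
               "zero samples")
  expect_error(partition_across_nodes(st, 2, proportions = c(0.7, 0.2)),
               "sum to 1")
})
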