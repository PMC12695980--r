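test_that("the ridge grid follows the heritability-fraction parameterization", {
  g <- build_ridge_grid(M = 1000, B = 10, R = 5)
  expect_equal(g$h, c(0.01, 0.255, 0.5, 0.745, 0.99))
  expect_equal(g$lambda[3], 1000 * 0.75 / 0.25)  # 3000
  expect_equal(g$omega[3], (10 * 5 / 1000) * 3000)  # 150
  expect_true(all(diff(g$lambda) < 0))
  expect_equal(g$omega, (g$B * g$R / g$M) * g$lambda)
  expect_error(build_ridge_grid(1000, 10, R = 1), "R >= 2")
})

test_that("vertical blocks are contiguous with the remainder in the last", {
  b <- make_blocks(10, 4)
  expect_equal(b$size, c(4L, 4L, 2L))
  expect_equal(nrow(make_blocks(5, 10)), 1L)
  expect_equal(unlist(Map(seq.int, b$from, b$to)), 1:10)
})

test_that("fold assignment is a seeded partition independent of node partitioning", {
  f <- fold_assignment(100, 5, shared_seed(3))
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(tabulate(f, 5), rep(20L, 5))
  expect_identical(f, fold_assignment(100, 5, shared_seed(3)))
  # labels depend only on the global index, not on node sizes
  expect_identical(f, fold_assignment(100, 5, shared_seed(3),
                                      node_sizes = c(50L, 50L)))
  expect_error(fold_assignment(10, 5, shared_seed(1), node_sizes = c(3L, 7L)),
               "empty fold")
})

test_that("Level-0 matches an independent per-fold normal-equations solve", {
  set.seed(20)
  X <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  folds <- rep(1:2, 3)
  grid <- build_ridge_grid(M = 2, B = 1, R = 2)
  l0 <- level0_fit_predict(X, y, make_blocks(2, 2), folds, grid)
  expect_equal(ncol(l0$W), 2L)  # B * R
  for (k in 1:2) for (r in 1:2) {
    tr <- folds != k
    beta <- ridge_oracle(X[tr, ], y[tr], grid$lambda[r])
    expect_equal(l0$W[folds == k, r], drop(X[folds == k, ] %*% beta),
                 tolerance = 1e-10)
  }
})

test_that("extreme shrinkage drives Level-0 predictions to zero", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  grid <- build_ridge_grid(M = 1e6, B = 1, R = 2)  # lambda_1 ~ 1e10
  l0 <- level0_fit_predict(X, y, make_blocks(3, 3), rep(1:2, 10), grid)
  expect_lt(max(abs(l0$W[, 1])), 1e-5)
})

test_that("Level-1 closed form matches the per-fold ridge oracle and selects by CV RSS", {
  set.seed(22)
  N <- 40
  W <- matrix(rnorm(N * 6), N, 6)
  y <- rnorm(N)
  folds <- rep(1:4, 10)
  grid <- build_ridge_grid(M = 600, B = 2, R = 3)
  l1 <- level1_fit(W, y, folds = folds, grid = grid)
  rss <- matrix(0, 4, 3)
  for (k in 1:4) {
    tr <- folds != k
    for (r in 1:3) {
      eta <- drop(solve(crossprod(W[tr, ]) + diag(grid$omega[r], 6),
                        crossprod(W[tr, ], y[tr])))
      rss[k, r] <- sum((y[!tr] - W[!tr, ] %*% eta)^2)
      if (r == l1$r_star)
        expect_equal(l1$eta[, k], eta, tolerance = 1e-9)
    }
  }
  expect_equal(l1$rss, rss, tolerance = 1e-9)
  expect_equal(l1$r_star, which.min(colSums(rss)))
  # global predictor stitches the per-fold predictions
  for (k in 1:4)
    expect_equal(l1$yhat[folds == k],
                 drop(W[folds == k, ] %*% l1$eta[, k]), tolerance = 1e-9)
})

test_that("a phenotype orthogonal to all features gives a null Level-1 fit", {
  set.seed(23)
  N <- 30
  W0 <- matrix(rnorm(N * 4), N, 4)
  y <- rnorm(N)
  folds <- rep(1:2, 15)
  # orthogonalize every column against y within each training complement
  W <- W0
  for (k in 1:2) {
    tr <- folds != k
    for (j in 1:4)
      W[tr, j] <- W0[tr, j] - sum(W0[tr, j] * y[tr]) / sum(y[tr]^2) * y[tr]
  }
  grid <- build_ridge_grid(M = 400, B = 2, R = 2)
  l1 <- level1_fit(W, y, folds = folds, grid = grid)
  expect_lt(max(abs(l1$eta)), 1e-10)
  expect_lt(max(abs(l1$yhat)), 1e-10)
})

test_that("the chi-squared statistic matches direct evaluation", {
  # orthogonal test vector: statistic 0, p = 1
  out0 <- chi2_test(cbind(c(1, 1, -1, -1)), c(1, -1, 1, -1), rep(0, 4), C = 1)
  expect_equal(out0$chisq, 0)
  expect_equal(out0$p, 1)
  # worked example: chi2 = 2^2 / ((2/3) * 4) = 1.5
  out <- chi2_test(cbind(c(1, -1, 1, -1)), c(1, -1, 0, 0), rep(0, 4), C = 1)
  expect_equal(out$chisq, 1.5)
  expect_equal(attr(out, "sigma2"), 2 / 3)
  # the QC threshold statistic maps to p = 1.0e-6 (2 s.f.)
  expect_equal(signif(pchisq(23.928, 1, lower.tail = FALSE), 2), 1.0e-6)
  expect_error(chi2_test(cbind(rep(0, 4)), rnorm(4), rep(0, 4), C = 1),
               "zero norm")
})

test_that("the statistic is invariant to sample permutation and sign flips", {
  set.seed(24)
  n <- 50
  xt <- matrix(rnorm(n * 3), n, 3)
  yt <- rnorm(n); yh <- rnorm(n, sd = 0.2)
  base <- chi2_test(xt, yt, yh, C = 2)
  perm <- sample(n)
  expect_equal(chi2_test(xt[perm, ], yt[perm], yh[perm], C = 2)$chisq,
               base$chisq, tolerance = 1e-12)
  expect_equal(chi2_test(-xt, yt, yh, C = 2)$chisq, base$chisq,
               tolerance = 1e-12)
})

test_that("duplicated SNP columns receive identical statistics", {
  st <- tiny_study(N = 150, M = 30, C = 1, P = 1, seed = 25, missing_rate = 0)
  j <- which(apply_filters(local_counts(st$X))$pass)[1]
  st$X <- cbind(st$X, st$X[, j])
  st$snp_info <- tibble::add_row(st$snp_info,
                                 snp_id = "snp_dup", chrom = 1L,
                                 pos = max(st$snp_info$pos) + 1000L,
                                 ancestral_freq = st$snp_info$ancestral_freq[j])
  st$nodes <- NULL
  fit <- run_plaintext_gwas(st, gwas_config(K = 3, R = 3, block_size = 31))
  res <- fit$results
  expect_equal(res$chisq[res$snp_id == "snp_dup"], res$chisq[j],
               tolerance = 1e-10)
})

test_that("a strongly planted causal SNP tops the association ranking", {
  cfg <- sim_config(n_samples = 400, n_snps = 200, n_causal = 1,
                    heritability = 0.2, missing_rate = 0, seed = 26)
  st <- simulate_study(cfg)
  fit <- run_plaintext_gwas(st, gwas_config(K = 4, R = 3, block_size = 50,
                                            seed = 26))
  res <- dplyr::filter(fit$results, !is.na(.data$chisq))
  causal_id <- st$truth$snp_id[st$truth$is_causal]
  expect_equal(res$snp_id[which.max(res$chisq)], causal_id)
})

test_that("fit accessors expose tidy results, a one-row summary and plots", {
  st <- tiny_study(N = 100, M = 30, seed = 27)
  fit <- run_plaintext_gwas(st, gwas_config(K = 3, R = 3, block_size = 10))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("snp_id", "maf", "chisq", "p") %in% names(td)))
  expect_equal(nrow(td), 30)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_retained, fit$n_retained)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_qq(fit), "ggplot")
})
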