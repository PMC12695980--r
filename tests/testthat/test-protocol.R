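test_that("the distributed pipeline equals the plaintext oracle on a small study", {
  st <- tiny_study(N = 120, M = 40, C = 2, P = 2, seed = 3)
  conf <- gwas_config(K = 3, R = 3, block_size = 15, seed = 3)
  fit_d <- run_ppgwas(st, conf)
  fit_p <- run_plaintext_gwas(st, conf)
  rel <- abs(fit_d$results$chisq - fit_p$results$chisq) /
    pmax(fit_p$results$chisq, 1e-10)
  expect_lt(max(rel, na.rm = TRUE), 1e-6)
  expect_identical(fit_d$r_star, fit_p$r_star)
  expect_equal(fit_d$sigma2, fit_p$sigma2, tolerance = 1e-8)
  expect_identical(fit_d$results$pass, fit_p$results$pass)
})

test_that("identity-encoding reduction matches closed-form Level-0 predictions", {
  # P = 1, pads 0, O = I: the protocol collapses to the plaintext algebra
  st <- tiny_study(N = 60, M = 12, C = 1, P = 1, seed = 18, missing_rate = 0)
  conf <- gwas_config(K = 2, R = 2, block_size = 12, seed = 18,
                      identity_encoding = TRUE, allow_insecure = TRUE)
  fit_d <- run_ppgwas(st, conf)
  fit_p <- run_plaintext_gwas(st, conf)
  expect_lt(max(abs(fit_d$results$chisq - fit_p$results$chisq), na.rm = TRUE),
            1e-6)
})

test_that("identity encoding is refused outside the test harness", {
  st <- tiny_study(N = 60, M = 12, P = 1, seed = 18)
  expect_error(run_ppgwas(st, gwas_config(identity_encoding = TRUE)),
               "refused")
})

test_that("results are invariant to the node partition", {
  st <- tiny_study(N = 150, M = 40, C = 2, P = 1, seed = 19)
  conf <- gwas_config(K = 3, R = 3, block_size = 20, seed = 19,
                      admm_tol = 2e-13, admm_max_iter = 3000)
  fits <- lapply(c(1, 3), function(P)
    run_ppgwas(partition_across_nodes(st, P), conf, audit_hashes = FALSE))
  expect_lt(max(abs(fits[[1]]$results$chisq - fits[[2]]$results$chisq),
                na.rm = TRUE), 1e-8)
})

test_that("SNP shuffling before the server test changes nothing after decoding", {
  st <- tiny_study(N = 100, M = 30, C = 1, P = 2, seed = 20)
  conf <- gwas_config(K = 3, R = 3, block_size = 15, seed = 20)
  fit_plain <- run_ppgwas(st, conf, audit_hashes = FALSE)
  conf$shuffle_snps <- TRUE
  fit_shuf <- run_ppgwas(st, conf, audit_hashes = FALSE)
  expect_equal(fit_shuf$results$chisq, fit_plain$results$chisq,
               tolerance = 1e-12)
})

test_that("the server transcript stays inside the payload catalogue", {
  st <- tiny_study(N = 120, M = 40, C = 2, P = 2, seed = 3)
  conf <- gwas_config(K = 3, R = 3, block_size = 15, seed = 3)
  fit <- run_ppgwas(st, conf)
  aud <- audit_transcript(fit)
  expect_true(aud$ok)
  expect_length(aud$bad_kinds, 0)
  expect_length(aud$bad_dims, 0)
  expect_length(aud$raw_leaks, 0)

  tr <- fit$transport$transcript()
  expect_true(all(tr$kind %in% payload_catalogue()))
  # expected message census for the staged protocol
  P <- 2; K <- conf$K
  B <- nrow(make_blocks(fit$n_retained, conf$block_size))
  census <- 2 * P +          # masked counts up + totals down
    2 * P +                  # masked moments
    3 * P + 2 * P +          # projection payloads + returns
    P * K +                  # Level-0 phenotype payloads
    2 * P * K * B +          # Level-0 design + gram payloads
    P * K +                  # association test vectors
    P                        # chi-squared return
  expect_equal(nrow(tr), census)
})

test_that("the audit detects a raw-data row if one were to leak", {
  st <- tiny_study(N = 60, M = 20, C = 1, P = 2, seed = 22)
  fit <- run_ppgwas(st, gwas_config(K = 2, R = 2, block_size = 10, seed = 22))
  expect_true(audit_transcript(fit)$ok)
  # simulate a leak: send one node's raw genotype slice through the transport
  fit$transport$send("node1", "server", "qc", "masked_counts",
                     st$nodes[[1]]$X)
  aud <- audit_transcript(fit)
  expect_false(aud$ok)
  expect_gt(length(aud$raw_leaks), 0)
})

test_that("unpartitioned studies are rejected", {
  st <- tiny_study(N = 40, M = 10, P = 1, seed = 1)
  st$nodes <- NULL
  expect_error(run_ppgwas(st), "not partitioned")
})
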