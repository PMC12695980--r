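test_that("local counts tabulate exactly", {
  X <- cbind(c(0L, 0L, 1L, 2L, NA))
  expect_equal(unname(local_counts(X)[1, ]), c(2L, 1L, 1L, 1L))
  expect_equal(unname(local_counts(cbind(rep(NA_integer_, 6)))[1, ]),
               c(0L, 0L, 0L, 6L))
  expect_error(local_counts(cbind(c(0L, 3L))), "out-of-range dosage")

  # loop oracle on a random column
  set.seed(4)
  x <- sample(c(0:2, NA), 200, replace = TRUE)
  oracle <- c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
              sum(x == 2, na.rm = TRUE), sum(is.na(x)))
  expect_equal(unname(local_counts(cbind(x))[1, ]), oracle)
})

test_that("count aggregation equals pooled tabulation, with and without masking", {
  expect_equal(unname(aggregate_counts(list(rbind(c(1L, 2L, 3L, 0L)),
                                            rbind(c(4L, 0L, 1L, 1L))))[1, ]),
               c(5L, 2L, 4L, 1L))
  one <- rbind(c(7L, 1L, 0L, 2L))
  expect_equal(unname(aggregate_counts(list(one))), unname(one))

  set.seed(8)
  Xs <- lapply(1:4, function(p)
    matrix(sample(c(0:2, NA), 25 * 30, replace = TRUE), 25, 30))
  per_node <- lapply(Xs, local_counts)
  pooled <- local_counts(do.call(rbind, Xs))
  expect_identical(unname(aggregate_counts(per_node)), unname(pooled))
  expect_identical(unname(aggregate_counts(per_node, seed = shared_seed(1))),
                   unname(pooled))

  expect_error(aggregate_counts(list(matrix(0L, 2, 4), matrix(0L, 3, 4))),
               "SNP count mismatch")
})

test_that("the HWE statistic matches direct goodness-of-fit arithmetic", {
  # perfect equilibrium
  expect_equal(as.numeric(hwe_chisq(rbind(c(250L, 500L, 250L, 0L)))), 0)
  # (400, 400, 200): p_alt = 0.4, expected (360, 480, 160)
  expect_equal(as.numeric(hwe_chisq(rbind(c(400L, 400L, 200L, 0L)))),
               1600 / 360 + 6400 / 480 + 1600 / 160)
  # monomorphic: statistic 0 with flag
  h <- hwe_chisq(rbind(c(100L, 0L, 0L, 5L)))
  expect_equal(as.numeric(h), 0)
  expect_true(attr(h, "monomorphic"))
  expect_error(hwe_chisq(rbind(c(0L, 0L, 0L, 10L))), "at least one called")
})

test_that("the default HWE threshold is the 1-df chi-squared quantile at p = 1e-6", {
  expect_equal(round(qchisq(1e-6, df = 1, lower.tail = FALSE), 3), 23.928)
  expect_equal(qc_thresholds()$max_hwe_chisq, 23.928)
})

test_that("filters apply the documented boundary semantics", {
  thr <- qc_thresholds()
  # MAF 0.0525 > 0.05 passes; 0.0275 fails
  rep1 <- apply_filters(rbind(c(900L, 95L, 5L, 0L)), thr)
  expect_equal(rep1$maf, 0.0525)
  expect_true(rep1$pass_maf)
  rep2 <- apply_filters(rbind(c(950L, 45L, 5L, 0L)), thr)
  expect_equal(rep2$maf, 0.0275)
  expect_false(rep2$pass_maf)
  # HWE 27.78 > 23.928 fails
  rep3 <- apply_filters(rbind(c(400L, 400L, 200L, 0L)), thr)
  expect_false(rep3$pass_hwe)
  expect_match(rep3$reason, "hwe")
  # missing rate: 'exceeding 0.1' is strict
  at_boundary <- apply_filters(rbind(c(630L, 180L, 90L, 100L)), thr)
  expect_equal(at_boundary$missing_rate, 0.1)
  expect_true(at_boundary$pass_missing)
  over <- apply_filters(rbind(c(629L, 180L, 90L, 101L)), thr)
  expect_false(over$pass_missing)
  expect_error(apply_filters(matrix(integer(0), 0, 4)), "empty pooled study")
})

test_that("QC is invariant to how the study is partitioned", {
  st <- tiny_study(N = 120, M = 50, seed = 12)
  counts_pooled <- local_counts(st$X)
  for (P in c(1, 3, 5)) {
    stp <- partition_across_nodes(st, P)
    per_node <- lapply(stp$nodes, function(nd) local_counts(nd$X))
    expect_identical(unname(aggregate_counts(per_node, seed = shared_seed(1))),
                     unname(counts_pooled))
  }
})

test_that("QC reports write as deterministic TSV", {
  st <- tiny_study(N = 80, M = 30, seed = 5)
  rep <- apply_filters(local_counts(st$X), qc_thresholds(),
                       snp_id = st$snp_info$snp_id)
  f1 <- tempfile(); f2 <- tempfile()
  write_qc_report(rep, f1); write_qc_report(rep, f2)
  expect_identical(readLines(f1), readLines(f2))
  df <- read.table(f1, sep = "\t", header = TRUE)
  expect_equal(nrow(df), 30)
  expect_named(df, c("snp_id", "missing_rate", "maf", "hwe_chisq", "pass",
                     "reason"))
  unlink(c(f1, f2))
})
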