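test_that("standardization statistics follow exactly from pooled counts", {
  st <- standardization_from_counts(rbind(c(250L, 500L, 250L, 0L)))
  expect_equal(st$mean, 1)
  expect_equal(st$sd, sqrt(0.5))
  # with missing entries the imputed mean equals the called mean
  st2 <- standardization_from_counts(rbind(c(40L, 40L, 20L, 10L)))
  expect_equal(st2$mean, 0.8)
  # count-derived moments equal direct moments of the mean-imputed column
  set.seed(2)
  x <- sample(c(0:2, NA), 500, replace = TRUE, prob = c(.5, .3, .15, .05))
  cts <- local_counts(cbind(x))
  stx <- standardization_from_counts(cts)
  xi <- ifelse(is.na(x), mean(x, na.rm = TRUE), x)
  expect_equal(stx$mean, mean(x, na.rm = TRUE))
  expect_equal(stx$sd, sqrt(mean((xi - mean(xi))^2)))
  expect_error(standardization_from_counts(rbind(c(10L, 0L, 0L, 0L))),
               "zero-variance")
})

test_that("phenotype moments pool exactly and reject constants", {
  m <- phenotype_moments(sum(c(1, 2, 3)), sum(c(1, 2, 3)^2), 3)
  expect_equal(m$mean, 2)
  expect_equal(m$sd, sqrt(2 / 3))
  expect_error(phenotype_moments(15, 45, 5), "constant phenotype")
})

test_that("the plaintext projector centers, scales and annihilates covariates", {
  # intercept only: centering then scaling by 1/SD
  X <- cbind(c(1, 2, 3))
  pr <- project_covariates_plaintext(X, matrix(numeric(0), 3, 0), c(5, 6, 10),
                                     stats = list(mean = 2, sd = sqrt(2 / 3)))
  expect_equal(drop(pr$Xt), c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(pr$C, 1L)

  st <- tiny_study(N = 60, M = 20, C = 3, seed = 14, missing_rate = 0)
  pr2 <- project_covariates_plaintext(st$X, st$Z, st$y)
  Z1 <- cbind(st$Z, 1)
  # orthogonality to the intercept-augmented covariates
  expect_lt(max(abs(crossprod(Z1, pr2$Xt))), 1e-6 * 60)
  expect_lt(max(abs(crossprod(Z1, pr2$yt))), 1e-6 * 60)
  # idempotence: projecting the projected genotypes changes nothing
  pr3 <- project_covariates_plaintext(pr2$Xt, st$Z, st$y,
                                      stats = list(mean = rep(0, 20),
                                                   sd = rep(1, 20)))
  expect_lt(max(abs(pr3$Xt - pr2$Xt)), 1e-10)
  # a column already orthogonal to Z1 is a fixed point (up to scaling)
  v <- pr2$Xt[, 1]
  prv <- project_covariates_plaintext(cbind(v), st$Z, st$y,
                                      stats = list(mean = 0, sd = 2))
  expect_lt(max(abs(prv$Xt - v / 2)), 1e-10)
})

test_that("rank-deficient covariates abort with the collinear columns named", {
  Z <- cbind(a = rnorm(30), b = 1:30)
  Z <- cbind(Z, c = Z[, "a"])
  expect_error(project_covariates_plaintext(matrix(rnorm(30), 30, 1), Z,
                                            rnorm(30),
                                            stats = list(mean = 0, sd = 1)),
               "collinear")
})

test_that("encoded projection round-trips through the server to the plaintext result", {
  st <- tiny_study(N = 30, M = 12, C = 3, P = 2, seed = 15, missing_rate = 0)
  counts <- local_counts(st$X)
  stats <- standardization_from_counts(counts)
  ymom <- phenotype_moments(sum(st$y), sum(st$y^2), 30)
  sizes <- vapply(st$nodes, `[[`, 0L, "n")
  offs <- vapply(st$nodes, `[[`, 0L, "offset")
  pk <- privgwas:::projection_keys(shared_seed(6), 30L, 12L, 4L, offs, sizes)
  pls <- lapply(1:2, function(p)
    privgwas:::encode_for_projection(st$nodes[[p]], pk, p, stats, ymom$sd))

  # the summed covariate payload equals the pooled encoded covariate matrix
  OZ <- pk$O_Z$O
  pooled_T <- OZ %*% cbind(st$Z, 1) %*% t(pk$O_Zp$O)
  expect_lt(max(abs(Reduce(`+`, lapply(pls, `[[`, "Z")) - pooled_T)), 1e-10)

  enc <- privgwas:::server_projection(pls, 4L)
  pr <- project_covariates_plaintext(st$X, st$Z, st$y, stats)
  for (p in 1:2) {
    dec <- privgwas:::decode_projection(enc[[p]], pk, p)
    rows <- seq.int(offs[p] + 1L, offs[p] + sizes[p])
    expect_lt(max(abs(dec$Xt - pr$Xt[rows, ])), 1e-8)
    expect_lt(max(abs(dec$yt - pr$yt[rows])), 1e-8)
  }

  # tampered permutation fails the seeded checksum
  pk_bad <- pk
  pk_bad$decoys[[1]]$perm <- rev(pk$decoys[[1]]$perm)
  expect_error(privgwas:::decode_projection(enc[[1]], pk_bad, 1), "checksum")
})

test_that("identity encodings reduce payloads to the raw standardized matrices", {
  st <- tiny_study(N = 20, M = 8, C = 2, P = 1, seed = 16, missing_rate = 0)
  stats <- standardization_from_counts(local_counts(st$X))
  ymom <- phenotype_moments(sum(st$y), sum(st$y^2), 20)
  pk <- privgwas:::projection_keys(shared_seed(1), 20L, 8L, 3L, 0L, 20L,
                                   identity_encoding = TRUE)
  pl <- privgwas:::encode_for_projection(st$nodes[[1]], pk, 1, stats, ymom$sd)
  expect_equal(pl$Z, unname(cbind(st$Z, 1)), ignore_attr = TRUE)
  expect_equal(pl$X, privgwas:::standardize_dosages(st$X, stats),
               ignore_attr = TRUE)
  expect_equal(drop(pl$y), st$y / ymom$sd)
})

test_that("single node without covariates yields the centered standardized phenotype", {
  st <- tiny_study(N = 25, M = 10, C = 0, P = 1, seed = 17, missing_rate = 0)
  counts <- local_counts(st$X)
  stats <- standardization_from_counts(counts)
  ymom <- phenotype_moments(sum(st$y), sum(st$y^2), 25)
  pk <- privgwas:::projection_keys(shared_seed(2), 25L, 10L, 1L, 0L, 25L)
  pl <- privgwas:::encode_for_projection(st$nodes[[1]], pk, 1, stats, ymom$sd)
  enc <- privgwas:::server_projection(list(pl), 1L)
  dec <- privgwas:::decode_projection(enc[[1]], pk, 1)
  expect_lt(max(abs(dec$yt - (st$y - mean(st$y)) / ymom$sd)), 1e-8)
  expect_lt(max(abs(colMeans(dec$Xt))), 1e-10)
})
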