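# Standardization of genotypes/phenotype and projection onto the null space
# of the intercept-augmented covariates Z1 = [Z | 1]:
#   X~ = (I - Z1 (Z1'Z1)^{-1} Z1') X S,   S = diag(1 / sd_j),
# executed either on pooled plaintext data (the oracle path) or through
# two-sided orthonormal obfuscation with server assistance. Mean-centering
# is absorbed by the intercept column of Z1, so standardization only needs
# the per-SNP scale, which is exactly recoverable from pooled genotype
# counts — no individual-level data leaves a node for it.

#' Per-SNP standardization statistics from pooled counts
#'
#' Means and population (divide-by-n) standard deviations of the mean-imputed
#' dosages, computed exactly from pooled genotype-class counts: the imputed
#' column mean equals the called-genotype mean `2 p`, and the second moment
#' adds `m^2` for each imputed entry.
#'
#' @param counts Pooled `M x 4` count matrix (post-QC).
#' @return List with numeric vectors `mean` and `sd`.
#' @export
#' @examples
#' standardization_from_counts(rbind(c(250, 500, 250, 0)))  # mean 1, sd sqrt(0.5)
standardization_from_counts <- function(counts) {
  counts <- as_counts(counts)
  n_total <- rowSums(counts)
  n_called <- rowSums(counts[, 1:3, drop = FALSE])
  if (any(n_called == 0))
    stopf("SNP with no called genotypes reached standardization")
  s1 <- counts[, "n_het"] + 2 * counts[, "n_hom_alt"]
  m <- s1 / n_called
  ss <- counts[, "n_het"] + 4 * counts[, "n_hom_alt"] + counts[, "n_missing"] * m^2
  v <- ss / n_total - m^2
  v[v < 0] <- 0
  if (any(v <= 0))
    stopf("zero-variance SNP reached standardization (QC should remove monomorphic SNPs)")
  list(mean = unname(m), sd = unname(sqrt(v)))
}

#' Phenotype moments from masked sums
#'
#' Mean and population standard deviation from the pooled `sum(y)` and
#' `sum(y^2)` — the two scalars the masked aggregation pools.
#'
#' @param sum_y,sum_y2 Pooled first and second moments.
#' @param n Pooled sample count.
#' @return List with `mean` and `sd`.
#' @export
phenotype_moments <- function(sum_y, sum_y2, n) {
  m <- sum_y / n
  v <- sum_y2 / n - m^2
  if (v <= 1e-12 * max(1, m^2))
    stopf("constant phenotype: zero variance")
  list(mean = m, sd = sqrt(v))
}

# Mean-impute and scale (no centering; the projector's intercept centers).
standardize_dosages <- function(X, stats) {
  Xs <- X
  storage.mode(Xs) <- "double"
  for (j in seq_len(ncol(Xs))) {
    nas <- is.na(Xs[, j])
    if (any(nas)) Xs[nas, j] <- stats$mean[j]
  }
  sweep(Xs, 2L, stats$sd, `/`)
}

augment_intercept <- function(Z) {
  cbind(Z, `(intercept)` = rep(1, nrow(Z)))
}

#' Plaintext covariate projection (oracle path)
#'
#' Projects standardized genotypes and phenotype onto the null space of the
#' intercept-augmented covariates:
#' `X~ = (I - Z1 (Z1'Z1)^{-1} Z1') X S`, and likewise for `y / s_y`.
#'
#' @param X Dosage matrix (`NA` allowed; mean-imputed via `stats`).
#' @param Z Covariate matrix (zero columns allowed; the intercept is always
#'   appended).
#' @param y Phenotype vector.
#' @param stats Optional standardization stats (defaults to count-derived
#'   stats of `X` itself).
#' @return List of class `projected_data`: `Xt`, `yt`, `stats`, `s_y`,
#'   `C` (columns of `Z1`, i.e. the residual degrees-of-freedom correction).
#' @export
project_covariates_plaintext <- function(X, Z, y, stats = NULL) {
  N <- nrow(X)
  Z1 <- augment_intercept(Z)
  dec <- qr(Z1)
  if (dec$rank < ncol(Z1)) {
    bad <- colnames(Z1)[dec$pivot[seq.int(dec$rank + 1L, ncol(Z1))]]
    stopf("covariates are rank deficient (collinear columns: %s)",
          paste(bad, collapse = ", "))
  }
  if (is.null(stats)) stats <- standardization_from_counts(local_counts(X))
  Xs <- standardize_dosages(X, stats)
  mom <- phenotype_moments(sum(y), sum(y^2), N)
  ys <- y / mom$sd
  Xt <- Xs - Z1 %*% solve(crossprod(Z1), crossprod(Z1, Xs))
  yt <- ys - drop(Z1 %*% solve(crossprod(Z1), crossprod(Z1, ys)))
  structure(list(Xt = Xt, yt = yt, stats = stats, s_y = mom$sd,
                 C = ncol(Z1)), class = "projected_data")
}

# ---------------------------------------------------------------------------
# Encoded path.  One global O_Z of size (N + k_Z) x N is derived from the
# shared seed; node p uses the column slice for its sample range, which is
# what makes the server-side sum over nodes equal the pooled encoded matrix.

projection_keys <- function(seed, N, M, C1, node_offsets, node_sizes,
                            identity_encoding = FALSE, avoid = integer(0)) {
  seed <- as_shared_seed(seed)
  if (identity_encoding) {
    kz <- kx <- kzp <- ky <- 0L; k_my <- 0L
  } else {
    kz  <- draw_pad(derive_seed(seed, "projection", "oz", "pad"),
                    d = N, avoid = avoid)
    kx  <- draw_pad(derive_seed(seed, "projection", "ox", "pad"),
                    d = M, avoid = avoid)
    kzp <- draw_pad(derive_seed(seed, "projection", "ozprime", "pad"),
                    d = C1, avoid = avoid)
    k_my <- draw_pad(derive_seed(seed, "projection", "decoy", "pad"),
                     range = 3:8)
    ky  <- draw_pad(derive_seed(seed, "projection", "oy", "pad"),
                    range = 4:16, d = 1L + k_my, avoid = avoid)
  }
  mk <- function(d, k, ...) {
    if (identity_encoding)
      structure(list(O = diag(d), d = as.integer(d), pad = 0L),
                class = "obfuscation_matrix")
    else make_obfuscation(d, k, derive_seed(seed, "projection", ...))
  }
  O_Z  <- mk(N, kz, "oz")
  O_X  <- mk(M, kx, "ox")
  O_Zp <- mk(C1, kzp, "ozprime")
  O_y  <- mk(1L + k_my, ky, "oy")
  # One global decoy matrix (N rows) and one shared permutation: the
  # cross-node sum in the server's projector correction only decodes when
  # every node pads with the same column arrangement, so node p uses the row
  # slice of a single seed-derived decoy set.
  decoy_global <- if (identity_encoding) {
    structure(list(M_y = matrix(numeric(0), N, 0L), perm = 1L,
                   k_ytilde = 1, k_my = 0L, checksum = FALSE),
              class = "phenotype_decoy")
  } else {
    make_decoy(N, k_my, seed, "projection", checksum = TRUE)
  }
  offsets <- node_offsets
  decoys <- lapply(seq_along(node_sizes), function(p) {
    rows <- seq.int(offsets[p] + 1L, offsets[p] + node_sizes[p])
    d <- decoy_global
    d$M_y <- d$M_y[rows, , drop = FALSE]
    d
  })
  list(seed = seed, N = N, M = M, C1 = C1,
       O_Z = O_Z, O_X = O_X, O_Zp = O_Zp, O_y = O_y, decoys = decoys,
       node_offsets = node_offsets, node_sizes = node_sizes,
       identity = identity_encoding)
}

oz_slice <- function(keys, p) {
  idx <- seq.int(keys$node_offsets[p] + 1L, keys$node_offsets[p] + keys$node_sizes[p])
  keys$O_Z$O[, idx, drop = FALSE]
}

#' Encode one node's data for the distributed projection
#'
#' Produces the three server-bound payloads
#' `O_Z Z1_p O_Z'^T`, `O_Z Xs_p O_X^T` and `O_Z [ys_p, M_y] rho O_y^T`,
#' where `Xs_p`/`ys_p` are the scaled (not yet centered) node slices and
#' `O_Z` enters through the node's sample-range column slice. Payload shapes
#' reveal only padded dimensions.
#'
#' @param node List with `X`, `Z`, `y`, `offset` (a `sim_study` node).
#' @param keys Shared-seed projection keys (internal; built by the protocol).
#' @param p Node index.
#' @param stats,s_y Pooled standardization statistics.
#' @return List of payload matrices `Z`, `X`, `y`.
#' @keywords internal
encode_for_projection <- function(node, keys, p, stats, s_y) {
  OZp <- oz_slice(keys, p)
  Z1 <- augment_intercept(node$Z)
  Xs <- standardize_dosages(node$X, stats)
  ys <- node$y / s_y
  Ypad <- pad_and_permute(ys, keys$decoys[[p]])
  list(
    Z = OZp %*% Z1 %*% t(keys$O_Zp$O),
    X = (OZp %*% Xs) %*% t(keys$O_X$O),
    y = OZp %*% Ypad %*% t(keys$O_y$O)
  )
}

pinv <- function(A, tol = NULL) {
  sv <- svd(A)
  tol <- tol %||% (max(dim(A)) * max(sv$d) * .Machine$double.eps)
  keep <- sv$d > tol
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

#' Server-side encoded covariate projection
#'
#' From the summed encoded covariate payload `T = sum_p O_Z Z1_p O_Z'^T` the
#' server forms the encoded projector correction `T^+` (Moore-Penrose; with
#' padded columns `T'T` is structurally rank `C+1` and literally singular)
#' and returns, per node, `O_Z X~_p O_X^T` and the analogous phenotype
#' payload. Aborts when `rank(T) < C + 1` (collinear covariates).
#'
#' @param payloads List (per node) of [encode_for_projection()] payloads.
#' @param C1 Number of intercept-augmented covariate columns (public).
#' @return List (per node) with encoded projected `X` and `y` payloads.
#' @keywords internal
server_projection <- function(payloads, C1) {
  Tm <- Reduce(`+`, lapply(payloads, `[[`, "Z"))
  sv <- svd(Tm)
  tol <- max(dim(Tm)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol * 1e3)
  if (rank < C1)
    stopf("protocol abort at projection: encoded covariate payload is rank %d < %d (collinear covariates)",
          rank, C1)
  Tp <- pinv(Tm)
  SX <- Reduce(`+`, lapply(payloads, `[[`, "X"))
  SY <- Reduce(`+`, lapply(payloads, `[[`, "y"))
  FX <- Tp %*% SX
  FY <- Tp %*% SY
  lapply(payloads, function(pl)
    list(X = pl$X - pl$Z %*% FX, y = pl$y - pl$Z %*% FY))
}

#' Decode a node's projected slice
#'
#' `X~_p = O_Zp^T Enc O_X`; the phenotype additionally un-permutes the
#' columns, verifies the seeded linear checksum and discards decoys.
#'
#' @param enc Encoded result for node `p` (from [server_projection()]).
#' @param keys,p Projection keys and node index.
#' @return List with `Xt` and `yt` for the node.
#' @keywords internal
decode_projection <- function(enc, keys, p) {
  OZp <- oz_slice(keys, p)
  Xt <- crossprod(OZp, enc$X) %*% keys$O_X$O
  Ydec <- crossprod(OZp, enc$y) %*% keys$O_y$O
  dec <- keys$decoys[[p]]
  yt <- unpad_phenotype(Ydec, dec,
                        check = if (dec$checksum) "checksum" else "none")
  list(Xt = Xt, yt = yt)
}
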