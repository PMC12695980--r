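# Randomized-encoding primitives: orthonormal obfuscation matrices with
# padded dimensions, seed-shared additive masks, and phenotype decoy
# padding/permutation. These are the building blocks every protocol stage
# encodes its payloads with.

#' Draw a padded dimension count
#'
#' Pad counts are drawn from the shared seed (uniformly on `8..64` by
#' default) so that padded payload dimensions do not reveal true block or
#' sample-slice sizes to the server.
#'
#' @param seed_int Derived integer seed (see [derive_seed()]).
#' @param range Integer range to draw from.
#' @param d Payload dimension the pad will be added to (for `avoid`).
#' @param avoid Dimensions the padded total `d + k` must not equal. The
#'   nodes know every private dimension, so they deterministically bump the
#'   pad until the padded shape coincides with none of them.
#' @return A single integer pad count.
#' @export
draw_pad <- function(seed_int, range = 8:64, d = 0L, avoid = integer(0)) {
  k <- with_stream(seed_int, sample(range, 1L))
  while ((d + k) %in% avoid) k <- k + 1L
  k
}

#' Construct an obfuscation matrix with exactly orthonormal columns
#'
#' Returns a `(d + k) x d` matrix `O` with `t(O) %*% O = I_d` to machine
#' precision, obtained as the Q factor of a seeded Gaussian matrix (sign-fixed
#' for determinism). Exact orthonormality is a strict special case of the
#' in-expectation condition the encoding requires, and makes every decode
#' exact rather than exact-in-expectation.
#'
#' @param d Payload dimension (`>= 1`).
#' @param k Non-negative pad count; `k = 0` gives a square orthogonal matrix.
#' @param seed_int Derived integer seed driving the Gaussian draw.
#' @return An object of class `obfuscation_matrix` with elements `O`, `d`,
#'   `pad`.
#' @export
#' @examples
#' O <- make_obfuscation(2, 3, derive_seed(shared_seed(1), "projection", "ox"))
#' max(abs(crossprod(O$O) - diag(2)))  # ~1e-16
make_obfuscation <- function(d, k, seed_int) {
  if (!is_count(d)) stopf("payload dimension d must be a positive integer")
  if (!is_count(k, min = 0L)) stopf("pad count k must be a non-negative integer")
  O <- with_stream(seed_int, {
    A <- matrix(rnorm((d + k) * d), d + k, d)
    dec <- qr(A)
    Q <- qr.Q(dec)
    s <- sign(diag(qr.R(dec)))
    s[s == 0] <- 1
    sweep(Q, 2L, s, `*`)
  })
  structure(list(O = O, d = as.integer(d), pad = as.integer(k)),
            class = "obfuscation_matrix")
}

#' @export
print.obfuscation_matrix <- function(x, ...) {
  cat(sprintf("<obfuscation matrix %d x %d (pad %d)>\n",
              x$d + x$pad, x$d, x$pad))
  invisible(x)
}

#' Seed-shared additive masks
#'
#' Every node can regenerate its own mask `r_i` and the mask total
#' `sum(r_i)` from the shared seed; the server can reconstruct neither.
#' Integer-valued masks keep masked sums of counts exact (all quantities stay
#' well inside the exactly-representable double range).
#'
#' @param seed A [shared_seed()] and `path` addressing this mask set.
#' @param path Character path labels (see [derive_seed()]).
#' @param dim Dimensions of each summand (vector for matrices, length-1 for
#'   vectors).
#' @param n_nodes Number of parties.
#' @param type `"integer"` for exact count masking, `"real"` for moments.
#' @param scale Magnitude of real-valued masks.
#' @return List with `masks` (length-`n_nodes` list) and `total`.
#' @export
make_masks <- function(seed, path, dim, n_nodes,
                       type = c("integer", "real"), scale = 1) {
  type <- match.arg(type)
  n <- prod(dim)
  masks <- lapply(seq_len(n_nodes), function(p) {
    sp <- do.call(derive_seed, c(list(seed), as.list(path),
                                 list(sprintf("node=%d", p), "mask")))
    m <- with_stream(sp, {
      if (type == "integer") round(runif(n, -2^40, 2^40)) else rnorm(n) * scale
    })
    if (length(dim) > 1L) array(m, dim) else m
  })
  list(masks = masks, total = Reduce(`+`, masks))
}

#' Addition-based masked aggregation
#'
#' Computes the element-wise sum of per-node arrays so that every node learns
#' the exact total while the server only ever handles `x_i + r_i` and the
#' masked grand total. This is the aggregation primitive behind distributed
#' QC counts and phenotype moments.
#'
#' @param x_list List of per-node numeric arrays of identical shape.
#' @param masks A mask set from [make_masks()] matching `x_list`.
#' @return List with `total` (the decoded exact sum), `masked` (the per-node
#'   server-view payloads) and `server_total`.
#' @export
#' @examples
#' m <- make_masks(shared_seed(7), c("qc"), dim = 3, n_nodes = 3)
#' masked_sum(list(c(3, 5, 7), c(1, 1, 1), c(0, 2, 4)), m)$total
masked_sum <- function(x_list, masks) {
  P <- length(x_list)
  if (length(masks$masks) != P)
    stopf("mask set is for %d nodes, data for %d", length(masks$masks), P)
  d1 <- dim(x_list[[1]]) %||% length(x_list[[1]])
  for (x in x_list) {
    if (!identical(dim(x) %||% length(x), d1))
      stopf("masked_sum: summand shape mismatch")
  }
  masked <- Map(`+`, x_list, masks$masks)
  server_total <- Reduce(`+`, masked)
  total <- server_total - masks$total
  if (all(vapply(x_list, is.integer, logical(1))))
    storage.mode(total) <- "integer"   # integer masking is exact
  list(total = total, masked = masked, server_total = server_total)
}

#' Phenotype decoy columns and column permutation
#'
#' Builds the decoy matrix `M_y`, the column permutation `rho` over
#' `1 + k_My` columns, and the non-zero constant `k_ytilde` used by the
#' Level-0 payloads — all from the shared seed. When `checksum = TRUE` (and
#' `k_My >= 2`) the last decoy column is reserved for a linear checksum
#' (`y + M_y[, 1]`) that survives any linear server-side transformation, so a
#' mis-permuted decode is detectable.
#'
#' @param n Number of rows (the node's sample count).
#' @param k_my Number of decoy columns.
#' @param seed,path Shared seed and path addressing this decoy set.
#' @param checksum Reserve the last decoy column for the linear checksum.
#' @return An object of class `phenotype_decoy`.
#' @export
make_decoy <- function(n, k_my, seed, path, checksum = FALSE) {
  if (!is_count(k_my, min = 0L)) stopf("k_my must be a non-negative integer")
  if (checksum && k_my < 2L)
    stopf("checksum decoys require k_my >= 2")
  sd_ <- do.call(derive_seed, c(list(seed), as.list(path), list("decoy")))
  sp_ <- do.call(derive_seed, c(list(seed), as.list(path), list("perm")))
  sk_ <- derive_seed(seed, "level0", "kconst")
  M <- if (k_my > 0L) with_stream(sd_, matrix(rnorm(n * k_my), n, k_my)) else
    matrix(numeric(0), n, 0L)
  perm <- with_stream(sp_, sample(k_my + 1L))
  k_y <- with_stream(sk_, runif(1, 0.5, 2) * sample(c(-1, 1), 1L))
  structure(list(M_y = M, perm = perm, k_ytilde = k_y,
                 k_my = as.integer(k_my), checksum = checksum),
            class = "phenotype_decoy")
}

#' Hide a phenotype among decoy columns
#'
#' Binds `y` with the decoy columns and permutes the columns so the
#' phenotype's position is uniform over the `1 + k_My` columns from the
#' server's view. [unpad_phenotype()] inverts it exactly.
#'
#' @param y Numeric vector (one node's phenotype slice).
#' @param decoy A [make_decoy()] object with matching row count.
#' @return Matrix `length(y) x (1 + k_My)`.
#' @export
pad_and_permute <- function(y, decoy) {
  stopifnot(inherits(decoy, "phenotype_decoy"))
  if (nrow(decoy$M_y) != length(y) && decoy$k_my > 0L)
    stopf("decoy has %d rows, phenotype %d", nrow(decoy$M_y), length(y))
  M <- decoy$M_y
  if (decoy$checksum) M[, decoy$k_my] <- y + M[, 1L]
  cbind(y, M, deparse.level = 0L)[, decoy$perm, drop = FALSE]
}

#' Recover a phenotype from its padded, permuted representation
#'
#' @param mat Padded matrix (possibly transformed by a linear map, e.g. the
#'   covariate projector applied server-side).
#' @param decoy The [make_decoy()] object used for padding.
#' @param check `"exact"` verifies untouched decoy columns (pure round trip);
#'   `"checksum"` verifies the linear checksum column (after a linear
#'   transformation); `"none"` skips verification.
#' @param tol Tolerance for the checksum check.
#' @return The phenotype column (numeric vector).
#' @export
unpad_phenotype <- function(mat, decoy, check = c("exact", "checksum", "none"),
                            tol = 1e-8) {
  check <- match.arg(check)
  stopifnot(inherits(decoy, "phenotype_decoy"))
  if (ncol(mat) != decoy$k_my + 1L)
    stopf("padded matrix has %d columns, expected %d", ncol(mat), decoy$k_my + 1L)
  un <- mat[, order(decoy$perm), drop = FALSE]   # original column order
  y <- un[, 1L]
  if (check == "exact" && decoy$k_my > 0L) {
    M <- decoy$M_y
    if (decoy$checksum) M[, decoy$k_my] <- y + M[, 1L]
    if (max(abs(un[, -1L, drop = FALSE] - M)) > tol)
      stopf("phenotype decode failed: decoy columns do not match (wrong permutation?)")
  }
  if (check == "checksum") {
    if (!decoy$checksum) stopf("decoy carries no checksum column")
    resid <- un[, decoy$k_my + 1L] - y - un[, 2L]
    scale <- max(1, max(abs(un)))
    if (max(abs(resid)) > tol * scale)
      stopf("phenotype decode failed the seeded checksum (wrong permutation?)")
  }
  y
}
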