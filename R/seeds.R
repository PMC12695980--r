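# Hierarchical shared-seed derivation.
#
# All parties other than the server hold one shared secret seed. Every piece
# of protocol randomness (obfuscation matrices, additive masks, decoys, fold
# shuffles, pad counts) is derived deterministically from (seed, path), where
# the path is a list of labels drawn from a fixed vocabulary, so that all
# nodes agree on the randomness without communicating and the server — which
# never sees the seed — can reconstruct none of it.

.label_vocab <- c(
  # stages
  "qc", "moments", "projection", "level0", "level1", "assoc", "transport",
  # indices
  "fold", "block", "penalty", "node", "snp",
  # objects
  "oz", "ozprime", "ox", "oy", "oytilde", "oxtilde",
  "mask", "decoy", "perm", "kconst", "pad", "folds", "shuffle", "checksum",
  # simulation
  "genotypes", "phenotype", "effects", "missing", "subpop", "partition",
  "covariates", "noise", "relatedness", "ancestral"
)

#' Shared protocol seed
#'
#' Wraps the integer seed that the computational nodes share and the server
#' never sees. All protocol randomness is derived from it via
#' [derive_seed()] / [derive_stream()].
#'
#' @param value A single finite integer-valued number.
#' @return An object of class `privgwas_seed`.
#' @export
#' @examples
#' ss <- shared_seed(42)
#' derive_seed(ss, "projection", "oz")
shared_seed <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stopf("shared seed must be a single finite number")
  structure(list(value = as.integer(value)), class = "privgwas_seed")
}

#' @export
print.privgwas_seed <- function(x, ...) {
  cat("<shared seed (value withheld from server role)>\n")
  invisible(x)
}

as_shared_seed <- function(x) {
  if (inherits(x, "privgwas_seed")) x else shared_seed(x)
}

check_path <- function(path) {
  if (length(path) == 0L) stopf("empty derivation path")
  labels <- sub("=.*$", "", path)
  bad <- setdiff(labels, .label_vocab)
  if (length(bad))
    stopf("unknown derivation label(s): %s", paste(bad, collapse = ", "))
  invisible(path)
}

#' Derive a child seed from the shared seed and a label path
#'
#' Deterministic: the same (seed, path) yields the same child seed on every
#' node; distinct paths yield unrelated-looking child seeds. Labels must come
#' from the fixed protocol vocabulary; indices are attached as `"label=value"`.
#'
#' @param seed A [shared_seed()] (or plain integer, coerced).
#' @param ... Character path elements, e.g. `"level0", "oxtilde", "block=3"`.
#' @return A single integer in `[1, 2^28]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  seed <- as_shared_seed(seed)
  path <- as.character(unlist(list(...), use.names = FALSE))
  check_path(path)
  key <- paste(c(format(seed$value), path), collapse = "/")
  hex <- digest::digest(key, algo = "xxhash32", serialize = FALSE)
  # 28 bits keeps strtoi() in integer range
  strtoi(substr(hex, 1L, 7L), base = 16L) + 1L
}

# Evaluate `code` under a derived RNG stream without touching the caller's
# global RNG state.
with_stream <- function(seed_int, code) {
  withr::with_seed(seed_int, code)
}

#' Draw from a derived randomness stream
#'
#' Returns the first `n` uniform draws of the stream addressed by
#' `(seed, path)`. Mostly useful for testing the derivation contract;
#' internally the same streams drive obfuscation matrices, masks and decoys.
#'
#' @inheritParams derive_seed
#' @param n Number of uniform draws.
#' @param path Character vector of path labels (see [derive_seed()]).
#' @return Numeric vector of length `n`.
#' @export
derive_stream <- function(seed, path, n = 100L) {
  with_stream(do.call(derive_seed, c(list(seed), as.list(path))), runif(n))
}
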