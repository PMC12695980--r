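# Party-communication layer. Two interchangeable backends:
#   * in-process — direct delivery with full transcript recording, the
#     deterministic test/CI path;
#   * TCP sockets — one port per node, length-prefixed binary frames,
#     little-endian IEEE-754 doubles in row-major order.
# Every message traverses the transcript hook, which is what the privacy
# assertions (payload-kind catalogue, padded-dimension check, raw-row hash
# audit) are built on.

#' Catalogue of server-visible payload kinds
#'
#' The closed list of message kinds the server role may see; the transcript
#' audit fails on anything else.
#' @return Character vector.
#' @export
payload_catalogue <- function() {
  c("masked_counts", "masked_counts_total",
    "masked_moments", "masked_moments_total",
    "proj_covariates", "proj_genotypes", "proj_phenotype",
    "proj_genotypes_result", "proj_phenotype_result",
    "admm_gram", "admm_design", "admm_phenotype",
    "assoc_test_vectors", "assoc_chisq")
}

# Payload kinds whose shapes carry padded (obfuscated) dimensions; the
# dimension audit applies to these. Count tables and the chi-squared return
# have fixed public shapes (M x 4 genotype classes, length-M results).
padded_kinds <- function() {
  c("masked_moments", "masked_moments_total",
    "proj_covariates", "proj_genotypes", "proj_phenotype",
    "proj_genotypes_result", "proj_phenotype_result",
    "admm_gram", "admm_design", "admm_phenotype", "assoc_test_vectors")
}

hash_rows <- function(m) {
  if (is.null(dim(m))) m <- matrix(as.double(m), 1L)
  storage.mode(m) <- "double"
  vapply(seq_len(nrow(m)),
         function(i) digest::digest(m[i, ], algo = "xxhash64"),
         character(1))
}

#' In-process transport
#'
#' Direct single-process delivery with transcript recording. When
#' `audit_hashes = TRUE`, a hash of every row of every server-visible
#' payload is retained so the raw-data non-exposure property can be checked
#' mechanically; `keep_payloads = TRUE` additionally retains payload copies.
#'
#' @param n_nodes Number of node parties.
#' @param audit_hashes Record per-row payload hashes for server-visible
#'   messages.
#' @param keep_payloads Retain full payload copies in the transcript.
#' @return A transport object (environment) with `send()`, `transcript()`,
#'   `server_row_hashes()`.
#' @export
transport_inprocess <- function(n_nodes, audit_hashes = TRUE,
                                keep_payloads = FALSE) {
  self <- new.env(parent = emptyenv())
  self$n_nodes <- n_nodes
  self$log <- vector("list", 256L)
  self$n <- 0L
  self$hashes <- character(0)
  self$payloads <- list()
  self$send <- function(from, to, stage, kind, payload) {
    if (self$n == length(self$log))
      self$log <- c(self$log, vector("list", length(self$log)))
    self$n <- self$n + 1L
    shape <- dim(payload) %||% length(payload)
    self$log[[self$n]] <- list(from = from, to = to, stage = stage,
                               kind = kind, shape = shape)
    server_visible <- identical(to, "server") || identical(from, "server")
    if (audit_hashes && server_visible && is.numeric(payload))
      self$hashes <- c(self$hashes, hash_rows(payload))
    if (keep_payloads && server_visible)
      self$payloads[[self$n]] <- payload
    invisible(payload)
  }
  self$transcript <- function() {
    msgs <- self$log[seq_len(self$n)]
    tibble(
      from = vapply(msgs, `[[`, "", "from"),
      to = vapply(msgs, `[[`, "", "to"),
      stage = vapply(msgs, `[[`, "", "stage"),
      kind = vapply(msgs, `[[`, "", "kind"),
      shape = vapply(msgs, function(m) paste(m$shape, collapse = "x"), "")
    )
  }
  self$server_row_hashes <- function() unique(self$hashes)
  class(self) <- "privgwas_transport"
  self
}

#' @export
print.privgwas_transport <- function(x, ...) {
  cat(sprintf("<in-process transport: %d nodes, %d messages logged>\n",
              x$n_nodes, x$n))
  invisible(x)
}

#' Audit a server transcript
#'
#' Mechanical stand-in for the protocol's privacy guarantees: (i) every
#' server-visible payload kind belongs to the closed catalogue; (ii) no
#' recorded payload dimension equals an unpadded private dimension (a node
#' sample count, the covariate count, or a block size); (iii) no row of any
#' server-visible payload hashes to a row of any node's raw genotype,
#' covariate or phenotype slice.
#'
#' @param transport A [transport_inprocess()] object after a protocol run
#'   (or a `gwas_fit` from [run_ppgwas()], whose transport is attached).
#' @param private_dims Integer vector of dimensions that must not appear
#'   (node sample counts, covariate count, block sizes).
#' @param raw_hashes Character vector of row hashes of the raw per-node
#'   data (see [hash_rows()]).
#' @return List of class `transcript_audit` with `ok`, `bad_kinds`,
#'   `bad_dims`, `raw_leaks`, `n_messages`.
#' @export
audit_transcript <- function(transport, private_dims = integer(0),
                             raw_hashes = character(0)) {
  if (inherits(transport, "gwas_fit")) {
    private_dims <- transport$private_dims %||% private_dims
    raw_hashes <- transport$raw_hashes %||% raw_hashes
    transport <- transport$transport
  }
  tr <- transport$transcript()
  sv <- tr$from == "server" | tr$to == "server"
  bad_kinds <- setdiff(unique(tr$kind[sv]), payload_catalogue())
  padded <- sv & tr$kind %in% padded_kinds()
  shapes <- lapply(strsplit(tr$shape[padded], "x"), as.integer)
  bad_dims <- sort(unique(unlist(lapply(shapes, intersect, private_dims))))
  raw_leaks <- intersect(transport$server_row_hashes(), raw_hashes)
  structure(list(ok = !length(bad_kinds) && !length(bad_dims) &&
                   !length(raw_leaks),
                 bad_kinds = bad_kinds, bad_dims = bad_dims,
                 raw_leaks = raw_leaks, n_messages = sum(sv)),
            class = "transcript_audit")
}

#' @export
print.transcript_audit <- function(x, ...) {
  cat(sprintf("<transcript audit: %d server-visible messages — %s>\n",
              x$n_messages, if (x$ok) "clean" else "VIOLATIONS"))
  if (length(x$bad_kinds))
    cat("  uncatalogued kinds:", paste(x$bad_kinds, collapse = ", "), "\n")
  if (length(x$bad_dims))
    cat("  unpadded dimensions observed:", paste(x$bad_dims, collapse = ", "), "\n")
  if (length(x$raw_leaks))
    cat(sprintf("  %d raw data row(s) leaked\n", length(x$raw_leaks)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Binary framing (TCP backend).  Frame layout:
#   magic   8 bytes  "PGWASv01"
#   hlen    int32 LE
#   header  hlen bytes of JSON: from, to, stage, kind, dtype, dim, checksum
#   payload dim-implied count of little-endian values, row-major

.frame_magic <- charToRaw("PGWASv01")

payload_bytes <- function(payload, dtype) {
  if (dtype == "double") {
    v <- if (is.null(dim(payload))) as.double(payload) else as.double(t(payload))
    writeBin(v, raw(), size = 8L, endian = "little")
  } else if (dtype == "integer") {
    v <- if (is.null(dim(payload))) as.integer(payload) else as.integer(t(payload))
    writeBin(v, raw(), size = 4L, endian = "little")
  } else {
    charToRaw(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  }
}

write_frame <- function(con, from, to, stage, kind, payload) {
  dtype <- if (is.character(payload) || is.list(payload)) "json"
           else if (is.integer(payload)) "integer" else "double"
  pb <- payload_bytes(payload, dtype)
  header <- jsonlite::toJSON(list(
    from = from, to = to, stage = stage, kind = kind, dtype = dtype,
    dim = as.integer(dim(payload) %||% length(payload)),
    bytes = length(pb),
    checksum = digest::digest(pb, algo = "xxhash64", serialize = FALSE)
  ), auto_unbox = TRUE)
  hb <- charToRaw(as.character(header))
  writeBin(.frame_magic, con)
  writeBin(length(hb), con, size = 4L, endian = "little")
  writeBin(hb, con)
  if (length(pb)) writeBin(pb, con)
  flush(con)
  invisible(NULL)
}

read_exact <- function(con, n, what = "raw") {
  out <- raw(0)
  while (length(out) < n) {
    chunk <- readBin(con, "raw", n - length(out))
    if (!length(chunk)) {
      Sys.sleep(0.01)
      chunk <- readBin(con, "raw", n - length(out))
      if (!length(chunk))
        stopf("transport: peer closed the connection mid-frame")
    }
    out <- c(out, chunk)
  }
  out
}

read_frame <- function(con) {
  magic <- read_exact(con, 8L)
  if (!identical(magic, .frame_magic))
    stopf("transport: bad frame magic (corrupt stream)")
  hlen <- readBin(read_exact(con, 4L), "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(read_exact(con, hlen)))
  pb <- if (header$bytes > 0) read_exact(con, header$bytes) else raw(0)
  if (!identical(digest::digest(pb, algo = "xxhash64", serialize = FALSE),
                 header$checksum))
    stopf("transport: frame checksum mismatch (corrupt payload)")
  payload <- switch(header$dtype,
    double = {
      v <- readBin(pb, "double", n = length(pb) / 8L, size = 8L,
                   endian = "little")
      if (length(header$dim) == 2L)
        matrix(v, header$dim[1L], header$dim[2L], byrow = TRUE) else v
    },
    integer = {
      v <- readBin(pb, "integer", n = length(pb) / 4L, size = 4L,
                   endian = "little")
      if (length(header$dim) == 2L)
        matrix(v, header$dim[1L], header$dim[2L], byrow = TRUE) else v
    },
    json = jsonlite::fromJSON(rawToChar(pb), simplifyVector = TRUE)
  )
  list(header = header, payload = payload)
}

#' Serialize/deserialize round trip of one message frame
#'
#' Exposed for testing the framing contract (bit-exact round trips,
#' checksum detection of corruption).
#' @param payload Numeric/integer vector or matrix, or a list (JSON-coded).
#' @param from,to,stage,kind Frame header fields.
#' @return The decoded frame (list with `header`, `payload`).
#' @export
frame_roundtrip <- function(payload, from = "node1", to = "server",
                            stage = "test", kind = "masked_counts") {
  tmp <- tempfile()
  con <- file(tmp, "wb")
  write_frame(con, from, to, stage, kind, payload)
  close(con)
  con <- file(tmp, "rb")
  on.exit({ close(con); unlink(tmp) })
  read_frame(con)
}

# TCP endpoints -------------------------------------------------------------

tcp_connect_server <- function(base_port, n_nodes, timeout = 60) {
  lapply(seq_len(n_nodes), function(p) {
    socketConnection(host = "localhost", port = base_port + p,
                     server = TRUE, blocking = TRUE, open = "a+b",
                     timeout = timeout)
  })
}

tcp_connect_node <- function(base_port, p, timeout = 60, retries = 50L) {
  for (i in seq_len(retries)) {
    con <- tryCatch(
      suppressWarnings(
        socketConnection(host = "localhost", port = base_port + p,
                         blocking = TRUE, open = "a+b", timeout = timeout)),
      error = function(e) NULL)
    if (!is.null(con)) return(con)
    Sys.sleep(0.2)
  }
  stopf("node %d could not reach the server on port %d", p, base_port + p)
}
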