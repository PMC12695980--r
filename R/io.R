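# On-disk formats: versioned blockwise genotype archives (magic header +
# JSON manifest + per-block gzip segments), study directories with a JSON
# manifest, and read-only PLINK .bed/.bim/.fam input. All round trips are
# lossless; the archive's internal layout is self-defined and versioned.

.archive_magic <- charToRaw("PGWBLK01")
.na_sentinel <- -9L

#' Write a genotype matrix as a blockwise archive
#'
#' Splits the matrix into vertical SNP blocks and stores each block as an
#' independently compressed segment (gzip), preceded by a JSON manifest.
#' Blocks may be dense (all entries) or sparse (indices of entries that are
#' non-zero or missing); both read back identically.
#'
#' @param X Dosage matrix (`{0, 1, 2, NA}`).
#' @param path Output file.
#' @param block_size SNPs per block.
#' @param encoding `"dense"`, `"sparse"`, or `"auto"` (sparse when fewer
#'   than 25% of entries are non-zero).
#' @return `path`, invisibly.
#' @export
write_blockwise_archive <- function(X, path, block_size = 1000L,
                                    encoding = c("auto", "dense", "sparse")) {
  encoding <- match.arg(encoding)
  blocks <- make_blocks(ncol(X), block_size)
  Xi <- X
  storage.mode(Xi) <- "integer"
  Xi[is.na(Xi)] <- .na_sentinel
  segs <- vector("list", nrow(blocks))
  encs <- character(nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    blk <- Xi[, seq.int(blocks$from[b], blocks$to[b]), drop = FALSE]
    enc <- if (encoding == "auto") {
      if (mean(blk != 0L) < 0.25) "sparse" else "dense"
    } else encoding
    raw_blk <- if (enc == "dense") {
      writeBin(as.integer(blk), raw(), size = 4L, endian = "little")
    } else {
      nz <- which(blk != 0L)
      writeBin(c(length(nz), nz, as.integer(blk[nz])), raw(),
               size = 4L, endian = "little")
    }
    segs[[b]] <- memCompress(raw_blk, "gzip")
    encs[b] <- enc
  }
  manifest <- jsonlite::toJSON(list(
    format = "privgwas-blockwise", version = 1L,
    n_rows = nrow(X), n_cols = ncol(X), block_size = as.integer(block_size),
    n_blocks = nrow(blocks), dtype = "int32", na_sentinel = .na_sentinel,
    encoding = encs,
    compressed_bytes = vapply(segs, length, 0L)
  ), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.archive_magic, con)
  mb <- charToRaw(as.character(manifest))
  writeBin(length(mb), con, size = 4L, endian = "little")
  writeBin(mb, con)
  for (s in segs) writeBin(s, con)
  invisible(path)
}

#' Read a blockwise genotype archive
#'
#' @param path Archive written by [write_blockwise_archive()].
#' @return List with `X` (the reassembled dosage matrix, `NA` for missing)
#'   and `manifest`.
#' @export
read_blockwise_archive <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic, .archive_magic))
    stopf("not a blockwise genotype archive: bad magic in %s", path)
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  man <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)))
  blocks <- make_blocks(man$n_cols, man$block_size)
  if (nrow(blocks) != man$n_blocks)
    stopf("archive manifest inconsistent: %d blocks promised, %d implied",
          man$n_blocks, nrow(blocks))
  X <- matrix(NA_integer_, man$n_rows, man$n_cols)
  for (b in seq_len(man$n_blocks)) {
    seg <- readBin(con, "raw", man$compressed_bytes[b])
    if (length(seg) < man$compressed_bytes[b])
      stopf("truncated archive: block %d missing from %s", b, path)
    v <- readBin(memDecompress(seg, "gzip"), "integer",
                 n = man$n_rows * blocks$size[b] + 1e6,
                 size = 4L, endian = "little")
    nc <- blocks$size[b]
    blk <- if (man$encoding[b] == "dense") {
      if (length(v) != man$n_rows * nc)
        stopf("archive block %d: dtype/shape mismatch", b)
      matrix(v, man$n_rows, nc)
    } else {
      nnz <- v[1L]
      if (length(v) != 1L + 2L * nnz)
        stopf("archive block %d: dtype/shape mismatch", b)
      m <- matrix(0L, man$n_rows, nc)
      if (nnz > 0) m[v[seq.int(2L, 1L + nnz)]] <- v[seq.int(2L + nnz, 1L + 2L * nnz)]
      m
    }
    blk[blk == man$na_sentinel] <- NA_integer_
    X[, seq.int(blocks$from[b], blocks$to[b])] <- blk
  }
  list(X = X, manifest = man)
}

#' Write a partitioned study to disk
#'
#' Creates one directory per node (blockwise genotype archive, covariate and
#' phenotype TSVs) plus global SNP metadata, the causal-truth table and a
#' JSON manifest recording sample counts, offsets and the configuration
#' digest.
#'
#' @param study A partitioned study ([simulate_study()]).
#' @param dir Output directory (created).
#' @param block_size SNPs per archive block.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, block_size = 1000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  P <- length(study$nodes)
  for (p in seq_len(P)) {
    nd <- study$nodes[[p]]
    ndir <- file.path(dir, sprintf("node%d", p))
    dir.create(ndir, showWarnings = FALSE)
    write_blockwise_archive(nd$X, file.path(ndir, "genotypes.pgb"),
                            block_size = block_size)
    write.table(as.data.frame(nd$Z), file.path(ndir, "covariates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(y = nd$y), file.path(ndir, "phenotype.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(as.data.frame(study$snp_info), file.path(dir, "snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(study$truth))
    write.table(as.data.frame(study$truth), file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- study$config
  manifest <- list(
    format = "privgwas-study", version = 1L,
    n_samples = nrow(study$X), n_snps = ncol(study$X),
    n_covariates = ncol(study$Z), n_nodes = P,
    node_sizes = vapply(study$nodes, `[[`, 0L, "n"),
    node_offsets = vapply(study$nodes, `[[`, 0L, "offset"),
    block_size = as.integer(block_size),
    config_digest = if (!is.null(cfg)) digest::digest(unclass(cfg)) else NULL,
    seed = if (!is.null(cfg)) cfg$seed else NULL
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

read_study_node <- function(dir, p) {
  ndir <- file.path(dir, sprintf("node%d", p))
  X <- read_blockwise_archive(file.path(ndir, "genotypes.pgb"))$X
  zpath <- file.path(ndir, "covariates.tsv")
  zlines <- readLines(zpath, warn = FALSE)
  Z <- if (length(zlines) < 2L || !nzchar(trimws(zlines[1L]))) {
    matrix(numeric(0), nrow(X), 0L)
  } else {
    as.matrix(read.table(zpath, sep = "\t", header = TRUE))
  }
  y <- read.table(file.path(ndir, "phenotype.tsv"), sep = "\t",
                  header = TRUE)$y
  list(X = X, Z = Z, y = y)
}

#' Read a study directory
#'
#' @param dir Directory written by [write_study()].
#' @return A partitioned study (same shape as [simulate_study()] output,
#'   without the generating config).
#' @export
read_study <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  nodes <- vector("list", man$n_nodes)
  off <- 0L
  for (p in seq_len(man$n_nodes)) {
    nd <- read_study_node(dir, p)
    nd$offset <- as.integer(man$node_offsets[p])
    nd$n <- nrow(nd$X)
    if (nd$n != man$node_sizes[p])
      stopf("study manifest inconsistent: node %d has %d samples, manifest says %d",
            p, nd$n, man$node_sizes[p])
    nodes[[p]] <- nd
    off <- off + nd$n
  }
  snp_info <- as_tibble(read.table(file.path(dir, "snps.tsv"), sep = "\t",
                                   header = TRUE))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    as_tibble(read.table(truth_path, sep = "\t", header = TRUE)) else NULL
  study <- list(X = do.call(rbind, lapply(nodes, `[[`, "X")),
                Z = do.call(rbind, lapply(nodes, `[[`, "Z")),
                y = unlist(lapply(nodes, `[[`, "y")),
                snp_info = snp_info, truth = truth, nodes = nodes,
                node_sizes = as.integer(man$node_sizes), manifest = man)
  class(study) <- "sim_study"
  study
}

#' Read PLINK .bed/.bim/.fam genotypes
#'
#' SNP-major .bed only (magic `0x6c 0x1b 0x01`). Two-bit codes map to
#' dosages of the BIM A1 allele: `00` → 2 (A1 homozygous), `10` → 1
#' (heterozygous), `11` → 0 (A2 homozygous), `01` → missing. The counted
#' allele is recorded per SNP in the metadata.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return List with `X` (`N x M` dosage matrix), `snp_info` (tibble with
#'   snp_id, chrom, pos, allele_a1, allele_a2, counted_allele), `fam`.
#' @export
read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stopf("missing PLINK file: %s", f)
  bimdf <- read.table(bim, sep = "\t", header = FALSE,
                      col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"))
  famdf <- read.table(fam, header = FALSE,
                      col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  N <- nrow(famdf); M <- nrow(bimdf)
  raw <- readBin(bed, "raw", file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:2], as.raw(c(0x6c, 0x1b))))
    stopf("%s is not a PLINK .bed file (bad magic)", bed)
  if (raw[3L] != as.raw(0x01))
    stopf("sample-major .bed files are not supported")
  bpc <- ceiling(N / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpc * M)
    stopf(".fam line count (%d) inconsistent with .bed payload (%d SNPs x %d bytes expected, %d found)",
          N, M, bpc, length(body))
  # per-byte lookup: 4 two-bit codes -> dosage of A1
  code_map <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  byte_lut <- t(vapply(0:255, function(x) {
    code_map[as.character(c(bitwAnd(x, 3L), bitwAnd(bitwShiftR(x, 2L), 3L),
                            bitwAnd(bitwShiftR(x, 4L), 3L),
                            bitwAnd(bitwShiftR(x, 6L), 3L)))]
  }, integer(4)))
  idx <- as.integer(body) + 1L
  X <- matrix(NA_integer_, N, M)
  for (j in seq_len(M)) {
    bytes <- idx[seq.int((j - 1L) * bpc + 1L, j * bpc)]
    vals <- t(byte_lut[bytes, , drop = FALSE])
    X[, j] <- as.integer(vals)[seq_len(N)]
  }
  snp_info <- tibble(snp_id = bimdf$snp_id, chrom = bimdf$chrom,
                     pos = bimdf$pos, allele_a1 = bimdf$a1,
                     allele_a2 = bimdf$a2, counted_allele = bimdf$a1)
  list(X = X, snp_info = snp_info, fam = as_tibble(famdf))
}
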