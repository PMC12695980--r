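# TCP party programs. The server and node programs follow exactly the same
# stage sequence (and the same floating-point summation order) as the
# in-process orchestrator in protocol.R, so the two backends produce
# identical results; only the delivery mechanism differs. One port per node.
#
# The server is launched with the public study parameters (N, retained SNP
# count, covariate count, grid settings) — the quantities the protocol
# treats as inferable by the server — and never with the shared seed.

tcp_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    stopf("protocol abort at stage %s: %s", stage, conditionMessage(e))
  })
}

#' TCP server program
#'
#' Accepts one connection per node and runs the server role of the full
#' protocol over the framed TCP transport. Holds only public parameters,
#' never the shared seed.
#'
#' @param base_port Nodes connect to `base_port + p`.
#' @param n_nodes Number of node parties.
#' @param public List of public parameters: `N`, `M_kept`, `C1`, `K`, `R`,
#'   `block_size`, `admm` settings (`ell`, `relax`, `max_iter`, `tol`),
#'   `cg_tol`.
#' @param timeout Socket timeout in seconds.
#' @return List with `chisq` (as computed server-side) and `transcript`.
#' @export
tcp_server_program <- function(base_port, n_nodes, public, timeout = 120) {
  cons <- tcp_connect_server(base_port, n_nodes, timeout = timeout)
  on.exit(lapply(cons, close), add = TRUE)
  tp <- transport_inprocess(n_nodes, audit_hashes = FALSE)
  P <- n_nodes
  recv <- function(p, stage, kind) {
    fr <- tcp_stage(stage, read_frame(cons[[p]]))
    if (!identical(fr$header$kind, kind))
      stopf("protocol abort at stage %s: expected %s from node %d, got %s",
            stage, kind, p, fr$header$kind)
    tp$send(paste0("node", p), "server", stage, kind, fr$payload)
    fr$payload
  }
  post <- function(p, stage, kind, payload) {
    tp$send("server", paste0("node", p), stage, kind, payload)
    tcp_stage(stage,
              write_frame(cons[[p]], "server", paste0("node", p), stage,
                          kind, payload))
  }

  # masked QC counts
  masked <- lapply(seq_len(P), function(p) recv(p, "qc", "masked_counts"))
  total <- Reduce(`+`, masked)
  for (p in seq_len(P)) post(p, "qc", "masked_counts_total", total)
  # masked phenotype moments
  masked <- lapply(seq_len(P), function(p) recv(p, "moments", "masked_moments"))
  total <- Reduce(`+`, masked)
  for (p in seq_len(P)) post(p, "moments", "masked_moments_total", total)

  # projection
  payloads <- lapply(seq_len(P), function(p) list(
    Z = recv(p, "projection", "proj_covariates"),
    X = recv(p, "projection", "proj_genotypes"),
    y = recv(p, "projection", "proj_phenotype")))
  enc <- tcp_stage("projection", server_projection(payloads, public$C1))
  for (p in seq_len(P)) {
    post(p, "projection", "proj_genotypes_result", enc[[p]]$X)
    post(p, "projection", "proj_phenotype_result", enc[[p]]$y)
  }
  rm(payloads, enc)

  # Level 0
  K <- public$K; R <- public$R
  blocks <- make_blocks(public$M_kept, public$block_size)
  B <- nrow(blocks)
  grid <- build_ridge_grid(public$M_kept, B, R)
  conf <- list(admm_relax = public$admm$relax,
               admm_max_iter = public$admm$max_iter,
               admm_tol = public$admm$tol)
  ypl <- lapply(seq_len(P), function(p)
    lapply(seq_len(K), function(k) recv(p, "level0", "admm_phenotype")))
  ysum <- lapply(seq_len(K), function(k)
    drop(Reduce(`+`, lapply(ypl, `[[`, k))))
  E <- lapply(seq_len(K), function(k) matrix(0, length(ysum[[k]]), B * R))
  for (b in seq_len(B)) {
    Rpl <- vector("list", P); Xpl <- vector("list", P)
    for (p in seq_len(P)) {
      Rpl[[p]] <- vector("list", K); Xpl[[p]] <- vector("list", K)
      for (k in seq_len(K)) {
        Xpl[[p]][[k]] <- recv(p, "level0", "admm_design")
        Rpl[[p]][[k]] <- recv(p, "level0", "admm_gram")
      }
    }
    l0 <- tcp_stage("level0",
                    server_level0_block(Rpl, Xpl, ypl, grid$lambda,
                                        public$admm$ell, conf))
    for (k in seq_len(K))
      E[[k]][, (b - 1L) * R + seq_len(R)] <- l0$preds[[k]]
  }

  # Level 1
  l1 <- tcp_stage("level1",
                  server_level1(E, ysum, grid$omega, public$N, public$C1,
                                public$cg_tol))

  # association
  num <- numeric(public$M_kept); den <- numeric(public$M_kept)
  for (k in seq_len(K)) {
    Vsum <- 0
    for (p in seq_len(P)) {
      V <- recv(p, "assoc", "assoc_test_vectors")
      den <- den + colSums(V^2)
      Vsum <- Vsum + V
    }
    num <- num + drop(crossprod(Vsum, l1$resid[[k]]))
  }
  if (any(den == 0)) stopf("protocol abort at assoc: test SNP with zero norm")
  chisq <- num^2 / (l1$sigma2_enc * den)
  for (p in seq_len(P)) post(p, "assoc", "assoc_chisq", chisq)
  list(chisq = chisq, transcript = tp$transcript(), r_star = l1$r_star)
}

#' TCP node program
#'
#' Runs one node's role of the protocol: loads the node's slice from a study
#' directory, performs all shared-seed keying locally, and exchanges only
#' encoded payloads with the server.
#'
#' @param study_dir Study directory (see [write_study()]).
#' @param p This node's index.
#' @param base_port Connects to `base_port + p`.
#' @param config A [gwas_config()] (or plain list coercible to one).
#' @param timeout Socket timeout in seconds.
#' @return The node's association results (tibble).
#' @export
tcp_node_program <- function(study_dir, p, base_port, config, timeout = 120) {
  man <- jsonlite::fromJSON(file.path(study_dir, "manifest.json"))
  nd <- read_study_node(study_dir, p)
  nd$offset <- as.integer(man$node_offsets[p])
  snp_info <- as_tibble(read.table(file.path(study_dir, "snps.tsv"),
                                   sep = "\t", header = TRUE))
  P <- man$n_nodes; N <- man$n_samples; M <- man$n_snps
  sizes <- as.integer(man$node_sizes); offsets <- as.integer(man$node_offsets)
  C1 <- ncol(nd$Z) + 1L
  seed <- config$seed
  con <- tcp_connect_node(base_port, p, timeout = timeout)
  on.exit(close(con), add = TRUE)
  say <- function(stage, kind, payload)
    write_frame(con, paste0("node", p), "server", stage, kind, payload)
  hear <- function(stage, kind) {
    fr <- tcp_stage(stage, read_frame(con))
    if (!identical(fr$header$kind, kind))
      stopf("protocol abort at stage %s: expected %s, got %s",
            stage, kind, fr$header$kind)
    fr$payload
  }

  # QC
  qmasks <- make_masks(seed, "qc", dim = c(M, 4L), n_nodes = P)
  counts <- local_counts(nd$X)
  say("qc", "masked_counts", counts + qmasks$masks[[p]])
  pooled_counts <- hear("qc", "masked_counts_total") - qmasks$total
  storage.mode(pooled_counts) <- "integer"
  colnames(pooled_counts) <- count_cols
  qc <- apply_filters(pooled_counts, config$qc, snp_id = snp_info$snp_id)
  keep <- which(qc$pass)
  if (!length(keep)) stopf("protocol abort at qc: QC removed every SNP")

  # private dimensions the padded payload shapes must avoid
  M_kept <- length(keep)
  blocks <- make_blocks(M_kept, config$block_size)
  avoid <- sort(unique(c(sizes, C1 - 1L, C1, blocks$size)))

  # moments (padded to hide dimensional coincidences)
  mom_dim <- 2L + if (isTRUE(config$identity_encoding)) 0L else
    draw_pad(derive_seed(seed, "moments", "pad"), d = 2L, avoid = avoid)
  mmasks <- make_masks(seed, "moments", dim = mom_dim, n_nodes = P,
                       type = "real", scale = 2^20)
  say("moments", "masked_moments",
      c(sum(nd$y), sum(nd$y^2), numeric(mom_dim - 2L)) + mmasks$masks[[p]])
  mom <- hear("moments", "masked_moments_total") - mmasks$total
  ymom <- phenotype_moments(mom[1L], mom[2L], N)
  stats <- standardization_from_counts(pooled_counts[keep, , drop = FALSE])

  # projection
  pkeys <- projection_keys(seed, N, M_kept, C1, offsets, sizes,
                           identity_encoding = isTRUE(config$identity_encoding),
                           avoid = avoid)
  pl <- encode_for_projection(list(X = nd$X[, keep, drop = FALSE], Z = nd$Z,
                                   y = nd$y, offset = nd$offset),
                              pkeys, p, stats, ymom$sd)
  say("projection", "proj_covariates", pl$Z)
  say("projection", "proj_genotypes", pl$X)
  say("projection", "proj_phenotype", pl$y)
  enc <- list(X = hear("projection", "proj_genotypes_result"),
              y = hear("projection", "proj_phenotype_result"))
  proj <- decode_projection(enc, pkeys, p)
  rm(pl, enc)

  # Level 0
  folds <- fold_assignment(N, config$K, seed, node_sizes = sizes)
  folds_p <- folds[seq.int(offsets[p] + 1L, offsets[p] + sizes[p])]
  layout <- fold_layout(folds, offsets, sizes)
  grid <- build_ridge_grid(M_kept, nrow(blocks), config$R)
  keys0 <- level0_keys(seed, layout, blocks,
                       identity_encoding = isTRUE(config$identity_encoding),
                       avoid = avoid)
  ell <- config$admm_ell %||% (N * (config$K - 1) / (2 * config$K * P))
  K <- config$K
  for (k in seq_len(K)) {
    pn <- layout[[k]]$per_node[[p]]
    say("level0", "admm_phenotype",
        drop(keys0$k_ytilde^2 * (keys0$Oy[[k]]$O[, pn$cols, drop = FALSE] %*%
                                   proj$yt[pn$local_rows])))
  }
  for (b in seq_len(nrow(blocks))) {
    cols <- seq.int(blocks$from[b], blocks$to[b])
    Q <- keys0$Q[[b]]$O
    for (k in seq_len(K)) {
      pn <- layout[[k]]$per_node[[p]]
      Oslice <- keys0$Oy[[k]]$O[, pn$cols, drop = FALSE]
      say("level0", "admm_design",
          (1 / keys0$k_ytilde) *
            (Oslice %*% proj$Xt[pn$local_rows, cols, drop = FALSE]) %*% t(Q))
      Xb_tr <- proj$Xt[folds_p != k, cols, drop = FALSE]
      Ginv <- chol2inv(chol(crossprod(Xb_tr) + diag(ell, length(cols))))
      say("level0", "admm_gram", (Q %*% Ginv) %*% t(Q))
    }
  }

  # association
  perm <- if (isTRUE(config$shuffle_snps))
    with_stream(derive_seed(seed, "assoc", "shuffle"), sample(M_kept))
  else seq_len(M_kept)
  for (k in seq_len(K))
    say("assoc", "assoc_test_vectors",
        node_assoc_payload(p, proj$Xt[, perm, drop = FALSE], keys0, layout, k))
  chisq <- hear("assoc", "assoc_chisq")[order(perm)]

  dplyr::left_join(
    dplyr::bind_cols(snp_info[, intersect(c("snp_id", "chrom", "pos"),
                                          names(snp_info))],
                     qc[, c("missing_rate", "maf", "hwe_chisq", "pass")]),
    tibble(snp_id = snp_info$snp_id[keep], chisq = chisq,
           p = pchisq(chisq, df = 1, lower.tail = FALSE)),
    by = "snp_id")
}

#' Run the protocol over loopback TCP
#'
#' Convenience harness: spawns the node programs as background R processes
#' (via \pkg{callr}) against a study directory and runs the server program
#' in this process. Produces results identical to the in-process backend.
#'
#' @param study_dir Study directory (see [write_study()]).
#' @param config A [gwas_config()].
#' @param base_port Base TCP port (node `p` uses `base_port + p`).
#' @param timeout Socket timeout in seconds.
#' @return List with `results` (node 1's association table), `server`
#'   (server-side output incl. transcript), `node_results` (all nodes).
#' @export
run_ppgwas_tcp <- function(study_dir, config = gwas_config(),
                           base_port = 42700L, timeout = 120) {
  if (!requireNamespace("callr", quietly = TRUE))
    stopf("the TCP harness needs the callr package")
  man <- jsonlite::fromJSON(file.path(study_dir, "manifest.json"))
  P <- man$n_nodes
  # public parameters: QC-retained SNP count is public (counts-based QC)
  pooled <- Reduce(`+`, lapply(seq_len(P), function(p)
    local_counts(read_study_node(study_dir, p)$X)))
  M_kept <- sum(apply_filters(pooled, config$qc)$pass)
  C1 <- ncol(read_study_node(study_dir, 1L)$Z) + 1L
  public <- list(N = man$n_samples, M_kept = M_kept, C1 = C1,
                 K = config$K, R = config$R, block_size = config$block_size,
                 admm = list(
                   ell = config$admm_ell %||%
                     (man$n_samples * (config$K - 1) / (2 * config$K * P)),
                   relax = config$admm_relax,
                   max_iter = config$admm_max_iter, tol = config$admm_tol),
                 cg_tol = config$cg_tol)
  procs <- lapply(seq_len(P), function(p)
    callr::r_bg(function(study_dir, p, base_port, config, timeout) {
      privgwas::tcp_node_program(study_dir, p, base_port, config, timeout)
    }, args = list(study_dir = study_dir, p = p, base_port = base_port,
                   config = config, timeout = timeout),
    package = TRUE))
  on.exit(lapply(procs, function(pr) if (pr$is_alive()) pr$kill()), add = TRUE)
  server <- tcp_server_program(base_port, P, public, timeout = timeout)
  for (pr in procs) pr$wait(timeout = timeout * 1000)
  node_results <- lapply(procs, function(pr) pr$get_result())
  list(results = node_results[[1L]], server = server,
       node_results = node_results)
}
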