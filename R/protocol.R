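# The distributed privacy-preserving pipeline:
#   A/B  masked QC counts and phenotype moments,
#   C    two-sided obfuscated covariate projection,
#   D    Level-0 ridge by consensus ADMM on encoded payloads,
#   E    Level-1 ridge by server-side conjugate gradients,
#   F    distributed single-SNP chi-squared testing,
# orchestrated over a transport that records the full server transcript.
# Node-side and server-side stage computations are factored so the
# in-process orchestrator and the TCP party programs share all algebra.

# ---- shared-seed Level-0/1 keying ------------------------------------------

fold_layout <- function(folds, node_offsets, node_sizes) {
  K <- max(folds); P <- length(node_sizes)
  lapply(seq_len(K), function(k) {
    idx <- which(folds == k)           # global sample indices of fold k
    per_node <- lapply(seq_len(P), function(p) {
      lo <- node_offsets[p]; hi <- node_offsets[p] + node_sizes[p]
      cols <- which(idx > lo & idx <= hi)   # contiguous within the fold order
      list(cols = cols, local_rows = idx[cols] - lo)
    })
    list(idx = idx, n = length(idx), per_node = per_node)
  })
}

level0_keys <- function(seed, layout, blocks, identity_encoding = FALSE,
                        avoid = integer(0)) {
  seed <- as_shared_seed(seed)
  K <- length(layout); B <- nrow(blocks)
  mk <- function(d, kind, lab) {
    if (identity_encoding)
      structure(list(O = diag(d), d = as.integer(d), pad = 0L),
                class = "obfuscation_matrix")
    else
      make_obfuscation(d, draw_pad(derive_seed(seed, "level0", kind, lab, "pad"),
                                   d = d, avoid = avoid),
                       derive_seed(seed, "level0", kind, lab))
  }
  k_yt <- if (identity_encoding) 1 else
    with_stream(derive_seed(seed, "level0", "kconst"),
                runif(1, 0.5, 2) * sample(c(-1, 1), 1L))
  list(
    k_ytilde = k_yt,
    Oy = lapply(seq_len(K), function(k) mk(layout[[k]]$n, "oytilde",
                                           sprintf("fold=%d", k))),
    Q = lapply(seq_len(B), function(b) mk(blocks$size[b], "oxtilde",
                                          sprintf("block=%d", b)))
  )
}

# ---- node-side stage computations ------------------------------------------

node_level0_payloads <- function(p, Xt_p, yt_p, folds_p, keys0, layout,
                                 blocks, ell) {
  K <- length(layout); B <- nrow(blocks)
  kyt <- keys0$k_ytilde
  Y <- vector("list", K)
  Xpl <- lapply(seq_len(K), function(k) vector("list", B))
  Rpl <- lapply(seq_len(K), function(k) vector("list", B))
  for (k in seq_len(K)) {
    pn <- layout[[k]]$per_node[[p]]
    Oslice <- keys0$Oy[[k]]$O[, pn$cols, drop = FALSE]
    Y[[k]] <- kyt^2 * (Oslice %*% yt_p[pn$local_rows])
    te <- folds_p == k
    for (b in seq_len(B)) {
      cols <- seq.int(blocks$from[b], blocks$to[b])
      Q <- keys0$Q[[b]]$O
      Xb_te <- Xt_p[pn$local_rows, cols, drop = FALSE]
      Xpl[[k]][[b]] <- (1 / kyt) * (Oslice %*% Xb_te) %*% t(Q)
      Xb_tr <- Xt_p[!te, cols, drop = FALSE]
      Ginv <- chol2inv(chol(crossprod(Xb_tr) + diag(ell, length(cols))))
      Rpl[[k]][[b]] <- (Q %*% Ginv) %*% t(Q)
    }
  }
  list(Y = Y, X = Xpl, R = Rpl)
}

node_assoc_payload <- function(p, Xt_p, keys0, layout, k) {
  pn <- layout[[k]]$per_node[[p]]
  keys0$Oy[[k]]$O[, pn$cols, drop = FALSE] %*%
    Xt_p[pn$local_rows, , drop = FALSE]
}

# ---- server-side stage computations ----------------------------------------

# One block's Level-0: consensus ADMM for all folds and the whole penalty
# grid, from the per-node encoded payloads. Returns the encoded out-of-fold
# prediction columns for this block.
server_level0_block <- function(Rpl, Xpl, Ypl, lambdas, ell, conf) {
  P <- length(Rpl); K <- length(Rpl[[1L]]); R <- length(lambdas)
  preds <- vector("list", K)
  info <- list(iterations = 0L, max_primal = 0, max_dual = 0)
  for (k in seq_len(K)) {
    g_list <- lapply(seq_len(P), function(p) {
      g <- 0
      for (kk in setdiff(seq_len(K), k))
        g <- g + crossprod(Xpl[[p]][[kk]], Ypl[[p]][[kk]])
      drop(g)
    })
    Rinv_list <- lapply(seq_len(P), function(p) Rpl[[p]][[k]])
    sol <- consensus_ridge_admm(Rinv_list, g_list, lambdas, ell,
                                relax = conf$admm_relax,
                                max_iter = conf$admm_max_iter,
                                tol = conf$admm_tol)
    info$iterations <- max(info$iterations, max(sol$iterations))
    info$max_primal <- max(info$max_primal, sol$primal)
    info$max_dual <- max(info$max_dual, sol$dual)
    Ek <- 0
    for (p in seq_len(P)) Ek <- Ek + Xpl[[p]][[k]] %*% sol$Z
    preds[[k]] <- Ek                         # (n_k + pad) x R, this block
  }
  list(preds = preds, info = info)
}

# Level-1: per-fold conjugate-gradient ridge solves on the encoded
# prediction Gram, grid selection by summed out-of-fold encoded RSS.
server_level1 <- function(E, ysum, omega, N, C1, cg_tol) {
  K <- length(E); R <- length(omega); BR <- ncol(E[[1L]])
  gram <- lapply(E, crossprod)
  xpy <- lapply(seq_len(K), function(k) drop(crossprod(E[[k]], ysum[[k]])))
  rss <- matrix(0, K, R)
  eta <- array(0, c(BR, K, R))
  for (k in seq_len(K)) {
    W <- Reduce(`+`, gram[-k])
    rhs <- Reduce(`+`, xpy[-k])
    for (r in seq_len(R)) {
      sol <- cg_ridge_solve(W, rhs, omega[r], tol = cg_tol)
      eta[, k, r] <- sol$x
      rss[k, r] <- sum((ysum[[k]] - E[[k]] %*% sol$x)^2)
    }
  }
  r_star <- which.min(colSums(rss))
  resid <- lapply(seq_len(K), function(k)
    drop(ysum[[k]] - E[[k]] %*% eta[, k, r_star]))
  sigma2_enc <- sum(vapply(resid, function(r) sum(r^2), 0)) / (N - C1)
  list(r_star = r_star, resid = resid, sigma2_enc = sigma2_enc, rss = rss)
}

# ---- the in-process protocol run -------------------------------------------

#' Run the distributed privacy-preserving GWAS protocol
#'
#' Executes the full pipeline — masked QC, obfuscated covariate projection,
#' Level-0 consensus ADMM, Level-1 conjugate-gradient ridge, distributed
#' chi-squared testing — across the study's node partition and one server
#' role, exchanging only encoded payloads. The result is algebraically
#' equivalent to [run_plaintext_gwas()] on the pooled data (up to the ADMM
#' solver tolerance), and the attached transcript supports
#' [audit_transcript()].
#'
#' @param study A partitioned study ([simulate_study()] or
#'   [partition_across_nodes()] output).
#' @param config A [gwas_config()]. `identity_encoding = TRUE` is refused
#'   unless `allow_insecure = TRUE` (reduction tests only).
#' @param audit_hashes Record payload row hashes for the raw-exposure audit.
#' @param keep_payloads Retain server-visible payload copies.
#' @return A `gwas_fit` (engine `"distributed"`) with `transport`,
#'   `private_dims`, `raw_hashes`, `admm_info` attached.
#' @export
#' @examples
#' st <- simulate_study(sim_config(n_samples = 90, n_snps = 40, n_nodes = 2,
#'                                 n_causal = 2, heritability = 0.4,
#'                                 missing_rate = 0, seed = 3))
#' fit <- run_ppgwas(st, gwas_config(K = 3, R = 3, block_size = 20))
#' audit_transcript(fit)$ok
run_ppgwas <- function(study, config = gwas_config(), audit_hashes = TRUE,
                       keep_payloads = FALSE) {
  if (config$identity_encoding && !config$allow_insecure)
    stopf(paste("identity encoding is a degenerate test-only mode and is",
                "refused; set allow_insecure = TRUE only inside a test harness"))
  nodes <- study$nodes
  if (is.null(nodes)) stopf("study is not partitioned; call partition_across_nodes()")
  P <- length(nodes)
  sizes <- vapply(nodes, `[[`, 0L, "n")
  offsets <- vapply(nodes, `[[`, 0L, "offset")
  N <- sum(sizes)
  M <- ncol(nodes[[1L]]$X)
  C1 <- ncol(nodes[[1L]]$Z) + 1L
  seed <- config$seed
  snp_info <- study$snp_info %||%
    tibble(snp_id = sprintf("snp%06d", seq_len(M)), chrom = 1L, pos = seq_len(M))
  tp <- transport_inprocess(P, audit_hashes = audit_hashes,
                            keep_payloads = keep_payloads)
  raw_hashes <- if (audit_hashes) unique(unlist(lapply(nodes, function(nd)
    c(hash_rows(nd$X), if (ncol(nd$Z)) hash_rows(nd$Z),
      digest::digest(as.double(nd$y), algo = "xxhash64"))))) else character(0)

  # --- stage A/B: masked QC counts ------------------------------------------
  qmasks <- make_masks(seed, "qc", dim = c(M, 4L), n_nodes = P)
  counts_p <- lapply(nodes, function(nd) local_counts(nd$X))
  for (p in seq_len(P))
    tp$send(paste0("node", p), "server", "qc", "masked_counts",
            counts_p[[p]] + qmasks$masks[[p]])
  server_counts <- Reduce(`+`, Map(`+`, counts_p, qmasks$masks))
  for (p in seq_len(P))
    tp$send("server", paste0("node", p), "qc", "masked_counts_total",
            server_counts)
  pooled_counts <- server_counts - qmasks$total
  storage.mode(pooled_counts) <- "integer"
  colnames(pooled_counts) <- count_cols
  qc <- apply_filters(pooled_counts, config$qc, snp_id = snp_info$snp_id)
  keep <- which(qc$pass)
  if (!length(keep)) stopf("protocol abort at qc: QC removed every SNP")

  # private dimensions the padded payload shapes must avoid
  M_kept <- length(keep)
  blocks <- make_blocks(M_kept, config$block_size)
  avoid <- sort(unique(c(sizes, C1 - 1L, C1, blocks$size)))

  # --- masked phenotype moments (padded to hide dimensional coincidences) ---
  mom_dim <- 2L + if (config$identity_encoding) 0L else
    draw_pad(derive_seed(seed, "moments", "pad"), d = 2L, avoid = avoid)
  mmasks <- make_masks(seed, "moments", dim = mom_dim, n_nodes = P,
                       type = "real", scale = 2^20)
  mom_p <- lapply(nodes, function(nd)
    c(sum(nd$y), sum(nd$y^2), numeric(mom_dim - 2L)))
  for (p in seq_len(P))
    tp$send(paste0("node", p), "server", "moments", "masked_moments",
            mom_p[[p]] + mmasks$masks[[p]])
  server_mom <- Reduce(`+`, Map(`+`, mom_p, mmasks$masks))
  for (p in seq_len(P))
    tp$send("server", paste0("node", p), "moments", "masked_moments_total",
            server_mom)
  mom <- server_mom - mmasks$total
  ymom <- phenotype_moments(mom[1L], mom[2L], N)
  stats <- standardization_from_counts(pooled_counts[keep, , drop = FALSE])

  # --- stage C: obfuscated covariate projection -----------------------------
  pkeys <- projection_keys(seed, N, M_kept, C1, offsets, sizes,
                           identity_encoding = config$identity_encoding,
                           avoid = avoid)
  payloads <- lapply(seq_len(P), function(p) {
    nd <- nodes[[p]]
    pl <- encode_for_projection(list(X = nd$X[, keep, drop = FALSE],
                                     Z = nd$Z, y = nd$y, offset = nd$offset),
                                pkeys, p, stats, ymom$sd)
    tp$send(paste0("node", p), "server", "projection", "proj_covariates", pl$Z)
    tp$send(paste0("node", p), "server", "projection", "proj_genotypes", pl$X)
    tp$send(paste0("node", p), "server", "projection", "proj_phenotype", pl$y)
    pl
  })
  enc <- server_projection(payloads, C1)
  proj <- lapply(seq_len(P), function(p) {
    tp$send("server", paste0("node", p), "projection",
            "proj_genotypes_result", enc[[p]]$X)
    tp$send("server", paste0("node", p), "projection",
            "proj_phenotype_result", enc[[p]]$y)
    decode_projection(enc[[p]], pkeys, p)
  })
  rm(payloads, enc)

  # --- stage D: Level-0 consensus ADMM --------------------------------------
  folds <- fold_assignment(N, config$K, seed, node_sizes = sizes)
  folds_p <- lapply(seq_len(P), function(p)
    folds[seq.int(offsets[p] + 1L, offsets[p] + sizes[p])])
  layout <- fold_layout(folds, offsets, sizes)
  B <- nrow(blocks)
  grid <- build_ridge_grid(M_kept, B, config$R)
  keys0 <- level0_keys(seed, layout, blocks,
                       identity_encoding = config$identity_encoding,
                       avoid = avoid)
  # default ADMM penalty: about half the per-node training Gram diagonal
  ell <- config$admm_ell %||% (N * (config$K - 1) / (2 * config$K * P))
  K <- config$K; R <- config$R

  # Y payloads once per (p, k)
  ypl <- lapply(seq_len(P), function(p) {
    lapply(seq_len(K), function(k) {
      pn <- layout[[k]]$per_node[[p]]
      # plain vectors: a 1-column matrix shape would expose a literal "1"
      v <- drop(keys0$k_ytilde^2 *
                  (keys0$Oy[[k]]$O[, pn$cols, drop = FALSE] %*%
                     proj[[p]]$yt[pn$local_rows]))
      tp$send(paste0("node", p), "server", "level0", "admm_phenotype", v)
      v
    })
  })
  ysum <- lapply(seq_len(K), function(k)
    drop(Reduce(`+`, lapply(ypl, `[[`, k))))

  E <- lapply(seq_len(K), function(k)
    matrix(0, length(ysum[[k]]), B * R))
  admm_info <- list(iterations = 0L, max_primal = 0, max_dual = 0)
  for (b in seq_len(B)) {
    cols <- seq.int(blocks$from[b], blocks$to[b])
    Q <- keys0$Q[[b]]$O
    Rpl <- vector("list", P); Xpl <- vector("list", P)
    for (p in seq_len(P)) {
      Xt_p <- proj[[p]]$Xt
      Rpl[[p]] <- vector("list", K); Xpl[[p]] <- vector("list", K)
      for (k in seq_len(K)) {
        pn <- layout[[k]]$per_node[[p]]
        Oslice <- keys0$Oy[[k]]$O[, pn$cols, drop = FALSE]
        Xpl[[p]][[k]] <- (1 / keys0$k_ytilde) *
          (Oslice %*% Xt_p[pn$local_rows, cols, drop = FALSE]) %*% t(Q)
        te <- folds_p[[p]] == k
        Xb_tr <- Xt_p[!te, cols, drop = FALSE]
        Ginv <- chol2inv(chol(crossprod(Xb_tr) + diag(ell, length(cols))))
        Rpl[[p]][[k]] <- (Q %*% Ginv) %*% t(Q)
        tp$send(paste0("node", p), "server", "level0", "admm_design",
                Xpl[[p]][[k]])
        tp$send(paste0("node", p), "server", "level0", "admm_gram",
                Rpl[[p]][[k]])
      }
    }
    l0 <- server_level0_block(Rpl, Xpl, ypl, grid$lambda, ell, config)
    for (k in seq_len(K))
      E[[k]][, (b - 1L) * R + seq_len(R)] <- l0$preds[[k]]
    admm_info$iterations <- max(admm_info$iterations, l0$info$iterations)
    admm_info$max_primal <- max(admm_info$max_primal, l0$info$max_primal)
    admm_info$max_dual <- max(admm_info$max_dual, l0$info$max_dual)
  }

  # --- stage E: Level-1 CGD --------------------------------------------------
  l1 <- server_level1(E, ysum, grid$omega, N, C1, config$cg_tol)

  # --- stage F: distributed association test --------------------------------
  perm <- if (config$shuffle_snps)
    with_stream(derive_seed(seed, "assoc", "shuffle"), sample(M_kept))
  else seq_len(M_kept)
  num <- numeric(M_kept); den <- numeric(M_kept)
  for (k in seq_len(K)) {
    Vsum <- 0
    for (p in seq_len(P)) {
      V <- node_assoc_payload(p, proj[[p]]$Xt[, perm, drop = FALSE],
                              keys0, layout, k)
      tp$send(paste0("node", p), "server", "assoc", "assoc_test_vectors", V)
      den <- den + colSums(V^2)
      Vsum <- Vsum + V
    }
    num <- num + drop(crossprod(Vsum, l1$resid[[k]]))
  }
  if (any(den == 0)) stopf("protocol abort at assoc: test SNP with zero norm")
  chisq_perm <- num^2 / (l1$sigma2_enc * den)
  for (p in seq_len(P))
    tp$send("server", paste0("node", p), "assoc", "assoc_chisq", chisq_perm)
  chisq <- chisq_perm[order(perm)]   # nodes undo the shuffle
  pvals <- pchisq(chisq, df = 1, lower.tail = FALSE)
  sigma2 <- l1$sigma2_enc / keys0$k_ytilde^4

  results <- dplyr::left_join(
    dplyr::bind_cols(snp_info[, intersect(c("snp_id", "chrom", "pos"),
                                          names(snp_info))],
                     qc[, c("missing_rate", "maf", "hwe_chisq", "pass")]),
    tibble(snp_id = snp_info$snp_id[keep], chisq = chisq, p = pvals),
    by = "snp_id")
  structure(list(results = results, qc = qc, grid = grid, folds = folds,
                 r_star = l1$r_star, sigma2 = sigma2, rss = l1$rss,
                 config = config, n_samples = N, n_retained = M_kept,
                 C = C1, engine = "distributed", transport = tp,
                 admm_info = admm_info,
                 private_dims = sort(unique(c(sizes, ncol(nodes[[1L]]$Z),
                                              blocks$size))),
                 raw_hashes = raw_hashes),
            class = "gwas_fit")
}
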