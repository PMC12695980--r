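# Distributed quality control: per-node genotype-class counts, masked
# aggregation, missingness / minor-allele-frequency / Hardy-Weinberg filters.
# Because the pooled counts decode exactly through the additive masking, the
# distributed QC decision equals QC on the pooled plaintext study SNP for
# SNP.

count_cols <- c("n_hom_ref", "n_het", "n_hom_alt", "n_missing")

#' Per-SNP genotype-class counts for one node
#'
#' Exact tabulation of reference-homozygous, heterozygous, alternate-
#' homozygous and missing entries per SNP column.
#'
#' @param X Dosage matrix with entries in `{0, 1, 2, NA}`.
#' @return Integer matrix `M x 4` with columns
#'   `n_hom_ref, n_het, n_hom_alt, n_missing`.
#' @export
#' @examples
#' local_counts(cbind(c(0L, 0L, 1L, 2L, NA)))
local_counts <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  vals <- X[!is.na(X)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stopf("out-of-range dosage: genotypes must be 0, 1, 2 or missing")
  out <- cbind(
    n_hom_ref = colSums(X == 0L, na.rm = TRUE),
    n_het     = colSums(X == 1L, na.rm = TRUE),
    n_hom_alt = colSums(X == 2L, na.rm = TRUE),
    n_missing = colSums(is.na(X))
  )
  storage.mode(out) <- "integer"
  rownames(out) <- colnames(X)
  out
}

#' Pool per-node SNP counts
#'
#' Element-wise sum across nodes. With a shared seed the sum is carried
#' through the addition-based masked aggregation (the server only handles
#' masked tables); integer masking keeps the pooled counts exact.
#'
#' @param count_list List of per-node `M x 4` count matrices (identical SNP
#'   order).
#' @param seed Optional [shared_seed()]; when supplied the aggregation is
#'   performed through [masked_sum()].
#' @return Pooled `M x 4` integer count matrix.
#' @export
aggregate_counts <- function(count_list, seed = NULL) {
  d1 <- dim(count_list[[1L]])
  for (ct in count_list)
    if (!identical(dim(ct), d1))
      stopf("SNP count mismatch across nodes: all nodes must report the same SNPs")
  if (is.null(seed)) {
    out <- Reduce(`+`, count_list)
  } else {
    m <- make_masks(as_shared_seed(seed), "qc", dim = d1,
                    n_nodes = length(count_list))
    out <- masked_sum(count_list, m)$total
  }
  storage.mode(out) <- "integer"
  colnames(out) <- count_cols
  out
}

#' Hardy-Weinberg equilibrium chi-squared statistic
#'
#' One-degree-of-freedom goodness-of-fit statistic
#' `sum((obs - exp)^2 / exp)` with expected genotype counts from the pooled
#' alternate-allele frequency, missing entries excluded. Monomorphic SNPs
#' (expected heterozygote count zero) get statistic 0 and a flag.
#'
#' @param counts `M x 4` count matrix (see [local_counts()]).
#' @return Numeric vector of statistics, with attribute `monomorphic`
#'   (logical vector).
#' @export
#' @examples
#' hwe_chisq(rbind(c(400, 400, 200, 0)))  # 27.777...
hwe_chisq <- function(counts) {
  counts <- as_counts(counts)
  n_called <- rowSums(counts[, 1:3, drop = FALSE])
  if (any(n_called < 1))
    stopf("HWE statistic requires at least one called genotype per SNP")
  p <- (2 * counts[, "n_hom_alt"] + counts[, "n_het"]) / (2 * n_called)
  mono <- p == 0 | p == 1
  e0 <- n_called * (1 - p)^2
  e1 <- n_called * 2 * p * (1 - p)
  e2 <- n_called * p^2
  stat <- numeric(nrow(counts))
  ok <- !mono
  stat[ok] <- (counts[ok, "n_hom_ref"] - e0[ok])^2 / e0[ok] +
    (counts[ok, "n_het"] - e1[ok])^2 / e1[ok] +
    (counts[ok, "n_hom_alt"] - e2[ok])^2 / e2[ok]
  attr(stat, "monomorphic") <- mono
  stat
}

as_counts <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, 1L)
  if (ncol(counts) != 4L) stopf("counts must have 4 columns")
  if (is.null(colnames(counts))) colnames(counts) <- count_cols
  counts
}

#' QC thresholds
#'
#' Defaults: SNPs with missing rate exceeding 0.1 are removed; only SNPs
#' with minor allele frequency strictly greater than 0.05 are retained; the
#' Hardy-Weinberg chi-squared statistic must not exceed 23.928 (the 1-df
#' chi-squared quantile at p = 1e-6).
#'
#' @param max_missing_rate,min_maf,max_hwe_chisq Filter thresholds.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missing_rate = 0.1, min_maf = 0.05,
                          max_hwe_chisq = 23.928) {
  if (!is_prob(max_missing_rate)) stopf("max_missing_rate must lie in [0, 1]")
  if (!is_prob(min_maf)) stopf("min_maf must lie in [0, 1]")
  if (!is.numeric(max_hwe_chisq) || max_hwe_chisq < 0)
    stopf("max_hwe_chisq must be non-negative")
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 max_hwe_chisq = max_hwe_chisq), class = "qc_thresholds")
}

#' Apply QC filters to pooled counts
#'
#' Keep rule: `missing_rate <= max_missing_rate` AND `maf > min_maf` AND
#' `hwe_chisq <= max_hwe_chisq`, with `maf = min(p, 1 - p)` from the pooled
#' alternate-allele frequency over called genotypes and the missing rate
#' over all pooled samples.
#'
#' @param counts Pooled `M x 4` count matrix.
#' @param thresholds A [qc_thresholds()].
#' @param snp_id Optional SNP identifiers.
#' @return A tibble (class `qc_report`) with per-SNP `missing_rate`, `maf`,
#'   `hwe_chisq`, `monomorphic`, per-filter flags, `pass` and `reason`.
#' @export
apply_filters <- function(counts, thresholds = qc_thresholds(),
                          snp_id = NULL) {
  counts <- as_counts(counts)
  if (nrow(counts) == 0L) stopf("empty pooled study: no SNPs to filter")
  n_total <- rowSums(counts)
  if (any(n_total == 0L)) stopf("empty pooled study: zero samples")
  n_called <- rowSums(counts[, 1:3, drop = FALSE])
  missing_rate <- counts[, "n_missing"] / n_total
  p <- ifelse(n_called > 0, (2 * counts[, "n_hom_alt"] + counts[, "n_het"]) /
                (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe <- rep(0, nrow(counts)); mono <- rep(TRUE, nrow(counts))
  called_ok <- n_called >= 1
  if (any(called_ok)) {
    h <- hwe_chisq(counts[called_ok, , drop = FALSE])
    hwe[called_ok] <- h
    mono[called_ok] <- attr(h, "monomorphic")
  }
  pass_missing <- missing_rate <= thresholds$max_missing_rate
  pass_maf <- !is.na(maf) & maf > thresholds$min_maf
  pass_hwe <- hwe <= thresholds$max_hwe_chisq
  pass <- pass_missing & pass_maf & pass_hwe
  reason <- dplyr::case_when(
    !pass_missing & !pass_maf ~ "missing_rate;maf",
    !pass_missing & !pass_hwe ~ "missing_rate;hwe",
    !pass_maf & !pass_hwe ~ "maf;hwe",
    !pass_missing ~ "missing_rate",
    !pass_maf ~ "maf",
    !pass_hwe ~ "hwe",
    TRUE ~ ""
  )
  out <- tibble(
    snp_id = snp_id %||% rownames(counts) %||% sprintf("snp%06d", seq_len(nrow(counts))),
    missing_rate = unname(missing_rate), maf = unname(maf),
    hwe_chisq = unname(hwe), monomorphic = unname(mono),
    pass_missing = unname(pass_missing), pass_maf = unname(pass_maf),
    pass_hwe = unname(pass_hwe), pass = unname(pass), reason = reason
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' Write a QC report as TSV
#'
#' @param report A [apply_filters()] report.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- as.data.frame(report[, c("snp_id", "missing_rate", "maf", "hwe_chisq",
                                 "pass", "reason")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
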