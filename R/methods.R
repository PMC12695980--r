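# broom-style accessors and plots for fitted GWAS objects.

#' @export
print.gwas_fit <- function(x, ...) {
  cat(sprintf("<%s stacked-ridge GWAS fit>\n",
              if (identical(x$engine, "distributed")) "distributed privacy-preserving"
              else "centralized plaintext"))
  cat(sprintf("  N = %d samples, %d/%d SNPs retained by QC\n",
              x$n_samples, x$n_retained, nrow(x$results)))
  cat(sprintf("  K = %d folds, R = %d penalties, B = %d blocks; selected r* = %d (h = %.3f)\n",
              x$config$K, x$grid$R, x$grid$B, x$r_star, x$grid$h[x$r_star]))
  cat(sprintf("  residual variance sigma2_e = %.4g (df = N - C = %d)\n",
              x$sigma2, x$n_samples - x$C))
  n_sig <- sum(x$results$p < x$config$sig_threshold, na.rm = TRUE)
  cat(sprintf("  %d SNP(s) below the genome-wide threshold p < %g\n",
              n_sig, x$config$sig_threshold))
  invisible(x)
}

#' Tidy per-SNP association results
#'
#' @param x A `gwas_fit`.
#' @param ... Unused.
#' @return Tibble with one row per SNP: identifiers, QC columns, `chisq`,
#'   `p` (`NA` for SNPs removed by QC).
#' @export
tidy.gwas_fit <- function(x, ...) x$results

#' One-row fit summary
#'
#' @param x A `gwas_fit`.
#' @param ... Unused.
#' @return One-row tibble: sample/SNP counts, grid selection, residual
#'   variance, significant-SNP count.
#' @export
glance.gwas_fit <- function(x, ...) {
  tibble(
    engine = x$engine,
    n_samples = x$n_samples,
    n_snps = nrow(x$results),
    n_retained = x$n_retained,
    K = x$config$K, R = x$grid$R, B = x$grid$B,
    r_star = x$r_star,
    h_star = x$grid$h[x$r_star],
    lambda_star = x$grid$lambda[x$r_star],
    sigma2_e = x$sigma2,
    n_significant = sum(x$results$p < x$config$sig_threshold, na.rm = TRUE)
  )
}

#' Manhattan plot of a GWAS fit
#'
#' @param object A `gwas_fit`.
#' @param ... Unused.
#' @return A ggplot object: `-log10(p)` by position, colored by chromosome,
#'   with the genome-wide significance line.
#' @export
autoplot.gwas_fit <- function(object, ...) {
  df <- dplyr::filter(object$results, !is.na(.data$p))
  df$chrom <- factor(df$chrom %||% 1L)
  ggplot2::ggplot(df, ggplot2::aes(x = seq_len(nrow(df)),
                                   y = -log10(.data$p),
                                   color = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(object$config$sig_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "SNP index", y = expression(-log[10](p)),
                  title = "Stacked-ridge association scan") +
    ggplot2::theme_minimal()
}

#' QQ plot of association p-values
#'
#' @param fit A `gwas_fit`.
#' @return A ggplot object comparing observed and uniform `-log10(p)`.
#' @export
plot_qq <- function(fit) {
  p <- sort(fit$results$p[!is.na(fit$results$p)])
  df <- tibble(expected = -log10(stats::ppoints(length(p))),
               observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
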