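#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: each gene's geometric mean across samples is
#' the pseudo-reference (genes containing any zero are excluded), and the
#' sample's factor is the median over genes of count / geometric mean.
#'
#' @param counts nonnegative integer matrix, genes x samples (>= 2 samples).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (!is.matrix(counts) || ncol(counts) < 2L)
    stop_input("'counts' must be a matrix with at least 2 samples")
  if (any(counts < 0, na.rm = TRUE))
    stop_input("'counts' must be nonnegative")
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    stop_input("no gene has all-positive counts; size factors are undefined")
  f <- apply(counts[use, , drop = FALSE], 2,
             function(cnt) stats::median(cnt / exp(log_gm[use])))
  if (any(f <= 0))
    stop_input("nonpositive size factor estimated; counts too sparse")
  f
}

#' Log2-normalize counts by size factors
#'
#' `log2(count / factor + pseudocount)`, monotone in the count.
#'
#' @param counts genes x samples count matrix.
#' @param factors positive per-sample factors, aligned with the columns (a
#'   named vector is matched by name).
#' @param pseudocount added before the log (default 1).
#' @return real-valued matrix of the same shape.
#' @export
normalize_log2 <- function(counts, factors, pseudocount = 1) {
  if (length(factors) != ncol(counts))
    stop_input("'factors' (%d) do not align with samples (%d)",
               length(factors), ncol(counts))
  if (!is.null(names(factors))) {
    if (!setequal(names(factors), colnames(counts)))
      stop_input("'factors' names do not match sample ids")
    factors <- factors[colnames(counts)]
  }
  if (any(factors <= 0)) stop_input("size factors must be positive")
  log2(sweep(counts, 2, factors, "/") + pseudocount)
}

#' Paired differential expression on normalized log2 counts
#'
#' Per gene, paired differences of normalized log2 values (diagnosis minus
#' remission) across the pairs; the log2 fold change is the mean difference,
#' the p-value comes from a two-sided paired t-test (df = n - 1), and FDR is
#' controlled by Benjamini-Hochberg. Genes whose normalized values are zero
#' in every sample (all-zero counts at pseudocount 1) are dropped.
#'
#' @param norm normalized log2 matrix from [normalize_log2()].
#' @param pairs diagnosis-remission pairs (>= 2), as in [paired_t_test()].
#' @param alpha FDR significance level.
#' @return data.frame (class `twinmeth_de`) with `gene`, `mean_expression`,
#'   `log2fc`, `p_value`, `p_fdr`, `significant`.
#' @export
paired_de <- function(norm, pairs, alpha = 0.05) {
  pairs <- as_pair_frame(pairs)
  if (nrow(pairs) < 2L)
    stop_input("at least 2 expression pairs are required")
  check_samples_present(c(pairs$diagnosis, pairs$remission), colnames(norm))

  keep <- rowSums(norm != 0) > 0
  norm <- norm[keep, , drop = FALSE]
  d <- norm[, pairs$diagnosis, drop = FALSE] -
       norm[, pairs$remission, drop = FALSE]
  n <- ncol(d)
  log2fc <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  degenerate <- sd_d == 0
  t_stat <- ifelse(degenerate, 0, log2fc / (sd_d / sqrt(n)))
  p <- ifelse(degenerate, ifelse(log2fc == 0, 1, 0),
              2 * stats::pt(-abs(t_stat), df = n - 1))
  p_fdr <- bh_adjust(p)

  out <- data.frame(
    gene = rownames(norm),
    mean_expression = unname(rowMeans(
      norm[, c(pairs$diagnosis, pairs$remission), drop = FALSE])),
    log2fc = unname(log2fc),
    p_value = unname(p),
    p_fdr = unname(p_fdr),
    significant = unname(p_fdr < alpha),
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "n_pairs") <- n
  class(out) <- c("twinmeth_de", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around the standard step-up procedure: sorted ascending,
#' adj_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' original order.
#'
#' @param p_values numeric vector of p-values in [0,1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values))
    stop_input("'p_values' must be numeric")
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad))
    stop_input("%d p-value(s) outside [0,1]", sum(bad))
  stats::p.adjust(p_values, method = "BH")
}
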