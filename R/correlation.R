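#' Pearson correlation between CpG methylation and gene expression
#'
#' For each candidate (probe, gene) pair, the Pearson correlation between the
#' probe's beta values and the gene's normalized log2 expression over the
#' samples with both assays (the three diagnosis-remission pairs by default in
#' the pipeline, n = 6). Two-sided p-values use the t transform
#' t = rho * sqrt((n - 2) / (1 - rho^2)) with df = n - 2; pairs where either
#' vector is constant are flagged degenerate and excluded from testing.
#' Multiplicity is controlled by Benjamini-Hochberg across all tested
#' candidate pairs (`p_corr`). A record passes when |rho| >= `rho_min` and
#' `p_corr` <= `alpha`; with so few samples the magnitude criterion alone does
#' not guarantee a small p, so both are applied (each toggleable in
#' [select_signature_genes()]).
#'
#' @param beta probes x samples beta matrix.
#' @param norm_expr genes x samples normalized log2 expression matrix.
#' @param candidates data.frame of candidate pairs with columns `probe_id`
#'   (or `probe`) and `gene`, optionally `region`.
#' @param samples sample ids present in both matrices (>= 3).
#' @param rho_min,alpha the pass criteria recorded on each row.
#' @return data.frame with `probe_id`, `gene`, `region`, `rho`, `p_value`,
#'   `p_corr`, `n_samples`, `degenerate`, `passes`.
#' @export
correlate_cpg_gene <- function(beta, norm_expr, candidates, samples,
                               rho_min = 0.7, alpha = 0.05) {
  if (length(samples) < 3L)
    stop_input("at least 3 samples with both assays are required")
  for (s in samples) {
    if (!s %in% colnames(beta))
      stop_input("sample '%s' has no methylation assay", s)
    if (!s %in% colnames(norm_expr))
      stop_input("sample '%s' has no expression assay", s)
  }
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(candidates) && "probe" %in% names(candidates))
    names(candidates)[names(candidates) == "probe"] <- "probe_id"
  if (!all(c("probe_id", "gene") %in% names(candidates)))
    stop_input("'candidates' needs columns probe_id and gene")
  if (nrow(candidates) == 0L)
    stop_input("'candidates' is empty")
  check_samples_present(unique(candidates$probe_id), rownames(beta), "probe")
  check_samples_present(unique(candidates$gene), rownames(norm_expr), "gene")

  n_cand <- nrow(candidates)
  rho <- p <- rep(NA_real_, n_cand)
  n_used <- integer(n_cand)
  degenerate <- logical(n_cand)
  for (i in seq_len(n_cand)) {
    x <- beta[candidates$probe_id[i], samples]
    y <- norm_expr[candidates$gene[i], samples]
    ok <- !is.na(x) & !is.na(y)
    n_used[i] <- sum(ok)
    if (n_used[i] < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      degenerate[i] <- TRUE
      next
    }
    r <- stats::cor(x[ok], y[ok])
    rho[i] <- r
    if (abs(r) < 1) {
      tt <- r * sqrt((n_used[i] - 2) / (1 - r^2))
      p[i] <- 2 * stats::pt(-abs(tt), df = n_used[i] - 2)
    } else {
      p[i] <- 0
    }
  }
  p_corr <- rep(NA_real_, n_cand)
  tested <- !degenerate
  p_corr[tested] <- bh_adjust(p[tested])
  passes <- !degenerate & !is.na(rho) & abs(rho) >= rho_min &
    !is.na(p_corr) & p_corr <= alpha

  data.frame(
    probe_id = candidates$probe_id,
    gene = candidates$gene,
    region = if ("region" %in% names(candidates)) candidates$region
             else NA_character_,
    rho = rho,
    p_value = p,
    p_corr = p_corr,
    n_samples = n_used,
    degenerate = degenerate,
    passes = passes,
    stringsAsFactors = FALSE
  )
}

#' Select signature genes from correlation records
#'
#' A gene enters the signature when it is significantly differentially
#' expressed and at least `min_cpgs` of its correlation records pass the
#' magnitude and multiplicity criteria. The correlation sign is `-` when all
#' passing records are negative (the typical promoter-hypermethylation
#' pattern), `+` when all are positive (the MACROD2-like exception) and
#' `mixed` otherwise (a PLEKHG5-like single discordant CpG).
#'
#' @param records output of [correlate_cpg_gene()].
#' @param de a DE table with columns `gene`, `log2fc`, `p_fdr`,
#'   `significant` (from [paired_de()] or supplied externally).
#' @param min_cpgs minimum number of passing CpGs per gene.
#' @param rho_min minimum |rho| per CpG.
#' @param alpha ceiling on the BH-adjusted correlation p-value.
#' @param use_rho,use_pcorr toggles for the two pass criteria.
#' @return data.frame sorted by DE `p_fdr`: `gene`, `n_cpgs`, `cpgs`
#'   (semicolon-joined probe ids), `correlation_sign`, `log2fc`, `p_fdr`.
#' @export
select_signature_genes <- function(records, de, min_cpgs = 3, rho_min = 0.7,
                                   alpha = 0.05, use_rho = TRUE,
                                   use_pcorr = TRUE) {
  if (!all(c("gene", "log2fc", "p_fdr") %in% names(de)))
    stop_input("'de' needs columns gene, log2fc, p_fdr")
  if (!"significant" %in% names(de))
    de$significant <- de$p_fdr < alpha
  pass <- !records$degenerate & !is.na(records$rho)
  if (use_rho) pass <- pass & abs(records$rho) >= rho_min
  if (use_pcorr) pass <- pass & !is.na(records$p_corr) & records$p_corr <= alpha

  rec <- records[pass, , drop = FALSE]
  sig_de <- de[de$significant, , drop = FALSE]
  rec <- rec[rec$gene %in% sig_de$gene, , drop = FALSE]
  if (nrow(rec) == 0L) {
    out <- data.frame(gene = character(0), n_cpgs = integer(0),
                      cpgs = character(0), correlation_sign = character(0),
                      log2fc = numeric(0), p_fdr = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  by_gene <- split(rec, rec$gene)
  keep <- names(by_gene)[vapply(by_gene, function(g)
    length(unique(g$probe_id)) >= min_cpgs, logical(1))]
  out <- do.call(rbind, lapply(keep, function(g) {
    r <- by_gene[[g]]
    probes <- sort(unique(r$probe_id))
    sign <- if (all(r$rho > 0)) "+" else if (all(r$rho < 0)) "-" else "mixed"
    i <- match(g, sig_de$gene)
    data.frame(gene = g, n_cpgs = length(probes),
               cpgs = paste(probes, collapse = ";"),
               correlation_sign = sign,
               log2fc = sig_de$log2fc[i], p_fdr = sig_de$p_fdr[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene = character(0), n_cpgs = integer(0),
                      cpgs = character(0), correlation_sign = character(0),
                      log2fc = numeric(0), p_fdr = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- out[order(out$p_fdr, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
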