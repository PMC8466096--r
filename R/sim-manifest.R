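#' Generate a synthetic 450K-style probe manifest
#'
#' Lays out probes on chromosomes with strictly increasing 1-based positions
#' and assigns gene/region annotations in the Illumina 450K manifest dialect
#' (semicolon-joined `UCSC_RefGene_Name` / `UCSC_RefGene_Group`). Signature
#' genes each receive exactly `cpgs_per_signature_gene` probes, placed in
#' promoter regions (TSS1500/TSS200) with probability `promoter_fraction`.
#' Composition-confounded probes are annotated to a gene pool disjoint from
#' both the signature genes and the planted methylation-independent DE genes,
#' so that downstream expression correlation can act as the specificity
#' filter. A skeleton truth table records the role of every probe and gene.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cpg_manifest`: a list with elements `manifest`
#'   (data.frame: IlmnID, CHR, MAPINFO, UCSC_RefGene_Name, UCSC_RefGene_Group),
#'   `truth_probes` (probe_id, is_signature, is_composition_confounded, gene)
#'   and `truth_genes` (gene, is_signature, is_de_planted).
#' @export
generate_manifest <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)

  n <- config$n_probes
  n_sig_probes <- config$n_signature_genes * config$cpgs_per_signature_gene
  probe_id <- sprintf("cg%08d", seq_len(n))
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))

  # gene pools: signature / planted methylation-independent DE / background.
  shuffled <- sample(genes)
  sig_genes <- shuffled[seq_len(config$n_signature_genes)]
  de_genes <- shuffled[config$n_signature_genes + seq_len(config$n_de_genes)]
  bg_genes <- setdiff(genes, c(sig_genes, de_genes))
  if (length(bg_genes) == 0L) bg_genes <- de_genes  # degenerate tiny configs

  # genomic layout: random chromosome, strictly increasing positions per chrom
  chr <- sample(as.character(1:22), n, replace = TRUE)
  pos <- integer(n)
  for (c_ in unique(chr)) {
    idx <- which(chr == c_)
    pos[idx] <- cumsum(sample(100:10000, length(idx), replace = TRUE))
  }

  # probe roles
  role <- rep("background", n)
  sig_idx <- integer(0)
  if (n_sig_probes > 0L) {
    sig_idx <- sample(n, n_sig_probes)
    role[sig_idx] <- "signature"
  }
  comp_idx <- integer(0)
  if (config$n_composition_probes > 0L) {
    free <- setdiff(seq_len(n), sig_idx)
    if (length(free) < config$n_composition_probes)
      config_error("n_composition_probes", "exceeds probes left after signature placement")
    comp_idx <- sample(free, config$n_composition_probes)
    role[comp_idx] <- "composition"
  }

  gene1 <- rep(NA_character_, n)
  region1 <- rep(NA_character_, n)
  non_promoter <- c("5'UTR", "1stExon", "Body", "3'UTR")
  bg_region_freq <- c(TSS1500 = 0.14, TSS200 = 0.11, `5'UTR` = 0.09,
                      `1stExon` = 0.06, Body = 0.45, `3'UTR` = 0.15)

  if (n_sig_probes > 0L) {
    gene1[sig_idx] <- rep(sig_genes, each = config$cpgs_per_signature_gene)
    in_prom <- stats::runif(n_sig_probes) < config$promoter_fraction
    region1[sig_idx] <- ifelse(in_prom,
                               sample(c("TSS1500", "TSS200"), n_sig_probes, replace = TRUE),
                               sample(non_promoter, n_sig_probes, replace = TRUE))
  }
  if (length(comp_idx)) {
    gene1[comp_idx] <- sample(bg_genes, length(comp_idx), replace = TRUE)
    region1[comp_idx] <- sample(names(bg_region_freq), length(comp_idx),
                                replace = TRUE, prob = bg_region_freq)
  }
  bg_idx <- which(role == "background")
  annotate_bg <- bg_idx[stats::runif(length(bg_idx)) < config$annotated_fraction]
  if (length(annotate_bg)) {
    gene1[annotate_bg] <- sample(c(bg_genes, de_genes), length(annotate_bg), replace = TRUE)
    region1[annotate_bg] <- sample(names(bg_region_freq), length(annotate_bg),
                                   replace = TRUE, prob = bg_region_freq)
  }

  # a configurable fraction of annotated probes carry a second gene annotation
  gene_col <- gene1
  region_col <- region1
  annotated <- which(!is.na(gene1))
  if (length(annotated)) {
    extra <- annotated[stats::runif(length(annotated)) < config$multi_gene_fraction]
    if (length(extra)) {
      g2 <- sample(bg_genes, length(extra), replace = TRUE)
      clash <- g2 == gene1[extra]
      if (any(clash)) g2[clash] <- sample(bg_genes, sum(clash), replace = TRUE)
      keep <- g2 != gene1[extra]
      extra <- extra[keep]; g2 <- g2[keep]
      r2 <- sample(names(bg_region_freq), length(extra), replace = TRUE,
                   prob = bg_region_freq)
      gene_col[extra] <- paste(gene1[extra], g2, sep = ";")
      region_col[extra] <- paste(region1[extra], r2, sep = ";")
    }
  }
  gene_col[is.na(gene_col)] <- ""
  region_col[is.na(region_col)] <- ""

  manifest <- data.frame(
    IlmnID = probe_id,
    CHR = chr,
    MAPINFO = pos,
    UCSC_RefGene_Name = gene_col,
    UCSC_RefGene_Group = region_col,
    stringsAsFactors = FALSE
  )

  truth_probes <- data.frame(
    probe_id = probe_id,
    is_signature = role == "signature",
    is_composition_confounded = role == "composition",
    gene = gene1,
    stringsAsFactors = FALSE
  )
  truth_genes <- data.frame(
    gene = genes,
    is_signature = genes %in% sig_genes,
    is_de_planted = genes %in% de_genes,
    stringsAsFactors = FALSE
  )

  structure(
    list(manifest = manifest, truth_probes = truth_probes,
         truth_genes = truth_genes, config = config),
    class = "cpg_manifest"
  )
}

#' @export
print.cpg_manifest <- function(x, ...) {
  cat(sprintf("Synthetic CpG manifest: %d probes (%d signature, %d composition-confounded), %d genes\n",
              nrow(x$manifest), sum(x$truth_probes$is_signature),
              sum(x$truth_probes$is_composition_confounded), nrow(x$truth_genes)))
  invisible(x)
}
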