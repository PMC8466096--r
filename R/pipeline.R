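#' Run the full twin methylome-transcriptome integration pipeline
#'
#' Orchestrates every stage on a dataset (typically from [simulate_dataset()]
#' or [read_dataset()]): the twin-contrast delta-beta filter, paired
#' diagnosis-remission replication, probe annotation, paired differential
#' expression (or an externally supplied DE table), CpG-gene Pearson
#' correlation, signature-gene selection, and the structural QC analyses
#' (Euclidean-distance clustering, targeted PCA with reference cells,
#' parental comparability). Sample roles are taken from the sample sheet:
#' the trio is the non-paired diagnosis/healthy/remission methylation
#' samples, replication pairs are the paired methylation samples, expression
#' pairs the paired expression samples, and correlation uses the samples with
#' both assays.
#'
#' @param dataset a `twinmeth_sim` object or a list with elements `beta`,
#'   `samples`, `counts`, `manifest` (and optionally `truth`).
#' @param delta_min,delta_max_healthy twin-filter thresholds.
#' @param effect_min replication effect-size threshold (strict >).
#' @param rep_alpha optional replication p-value cutoff (off by default).
#' @param de_alpha FDR level for differential expression.
#' @param min_cpgs,rho_min,corr_alpha signature selection criteria.
#' @param pseudocount pseudocount for log2 normalization.
#' @param de_table optional externally produced DE table (columns `gene`,
#'   `log2fc`, `p_fdr`) used verbatim instead of the internal paired DE stage.
#' @param linkage clustering linkage for the QC dendrogram.
#' @param parental_tolerance tolerance of the parental comparability check.
#' @param out_dir optional directory: all stage tables and the run report are
#'   written there as plain text.
#' @return object of class `twinmeth_run`: list with `report` (stage counts),
#'   `twin`, `replication`, `replicated`, `annotation`, `de`, `records`,
#'   `signature`, `qc`, `norm_expr`, `params`, `samples` and (if available)
#'   `truth`.
#' @seealso [gene_panels()], [evaluate_run()]
#' @export
run_pipeline <- function(dataset,
                         delta_min = 0.30, delta_max_healthy = 0.10,
                         effect_min = 0.30, rep_alpha = NULL,
                         de_alpha = 0.05, min_cpgs = 3, rho_min = 0.7,
                         corr_alpha = 0.05, pseudocount = 1,
                         de_table = NULL, linkage = "complete",
                         parental_tolerance = 0.10, out_dir = NULL) {
  for (el in c("beta", "samples", "counts", "manifest"))
    if (is.null(dataset[[el]]))
      stop_input("dataset lacks element '%s'", el)
  sm <- dataset$samples
  roles <- resolve_roles(sm)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  twin <- stage("filter-twin", twin_delta_filter(
    dataset$beta, roles$proband, roles$twin, roles$remission,
    delta_min = delta_min, delta_max_healthy = delta_max_healthy))

  rep_res <- stage("replicate", paired_t_test(dataset$beta, roles$meth_pairs))
  replicated <- stage("replicate", replicate_intersect(
    twin, rep_res, effect_min = effect_min, rep_alpha = rep_alpha))

  ann <- stage("annotate", annotate_probes(replicated$probe_id, dataset$manifest))

  if (is.null(de_table)) {
    sf <- stage("de", size_factors(dataset$counts))
    norm <- stage("de", normalize_log2(dataset$counts, sf, pseudocount))
    de <- stage("de", paired_de(norm, roles$expr_pairs, alpha = de_alpha))
  } else {
    de <- de_table
    if (!"significant" %in% names(de)) de$significant <- de$p_fdr < de_alpha
    sf <- stage("de", size_factors(dataset$counts))
    norm <- stage("de", normalize_log2(dataset$counts, sf, pseudocount))
  }

  overlap_genes <- intersect(unique(ann$gene), de$gene[de$significant])
  candidates <- unique(ann[ann$gene %in% overlap_genes,
                           c("probe_id", "gene", "region")])

  if (nrow(candidates) > 0L) {
    records <- stage("correlate", correlate_cpg_gene(
      dataset$beta, norm, candidates, roles$dna_rna_samples,
      rho_min = rho_min, alpha = corr_alpha))
    signature <- stage("correlate", select_signature_genes(
      records, de, min_cpgs = min_cpgs, rho_min = rho_min,
      alpha = corr_alpha))
  } else {
    records <- data.frame(probe_id = character(0), gene = character(0),
                          region = character(0), rho = numeric(0),
                          p_value = numeric(0), p_corr = numeric(0),
                          n_samples = integer(0), degenerate = logical(0),
                          passes = logical(0), stringsAsFactors = FALSE)
    signature <- select_signature_genes(records, de, min_cpgs = min_cpgs,
                                        rho_min = rho_min, alpha = corr_alpha)
  }
  signature_cpgs <- unique(unlist(strsplit(signature$cpgs, ";", fixed = TRUE)))

  qc <- stage("qc", run_qc(dataset, roles, replicated$probe_id,
                           signature_cpgs, linkage, parental_tolerance))

  promoter_fraction <- if (length(signature_cpgs))
    as.numeric(region_fraction(signature_cpgs, dataset$manifest)) else NA_real_

  report <- list(
    n_probes_input = nrow(dataset$beta),
    n_twin_filtered = sum(twin$retained),
    n_twin_hyper = sum(twin$retained & twin$direction == "hyper"),
    n_replicated = nrow(replicated),
    n_replicated_hyper = sum(replicated$direction == "hyper"),
    n_genes_annotated = attr(ann, "n_distinct_genes"),
    n_gene_regions_annotated = attr(ann, "n_distinct_gene_regions"),
    n_de_genes = sum(de$significant),
    n_de_up = sum(de$significant & de$log2fc > 0),
    n_de_down = sum(de$significant & de$log2fc < 0),
    n_overlap_genes = length(overlap_genes),
    n_signature_genes = nrow(signature),
    n_signature_cpgs = length(signature_cpgs),
    promoter_fraction = promoter_fraction,
    cluster_purity = qc$cluster$purity,
    parental_fraction_comparable =
      if (is.null(qc$parental)) NA_real_
      else attr(qc$parental, "fraction_comparable"),
    parameters = list(
      delta_min = delta_min, delta_max_healthy = delta_max_healthy,
      effect_min = effect_min, rep_alpha = rep_alpha, de_alpha = de_alpha,
      min_cpgs = min_cpgs, rho_min = rho_min, corr_alpha = corr_alpha,
      pseudocount = pseudocount, linkage = linkage,
      parental_tolerance = parental_tolerance),
    seed = if (!is.null(dataset$config)) dataset$config$seed else NULL
  )
  check_report_invariants(report)

  run <- structure(list(
    report = report, twin = twin, replication = rep_res,
    replicated = replicated, annotation = ann, de = de, records = records,
    signature = signature, signature_cpgs = signature_cpgs, qc = qc,
    norm_expr = norm, samples = sm, roles = roles,
    truth = dataset$truth
  ), class = "twinmeth_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# derive sample roles from the sample sheet
resolve_roles <- function(sm) {
  need <- c("sample_id", "subject_id", "condition", "pair_id",
            "has_methylation", "has_expression")
  if (!all(need %in% names(sm)))
    stop_input("sample sheet must have columns %s", paste(need, collapse = ", "))
  sm$pair_id[is.na(sm$pair_id)] <- ""
  trio <- sm[sm$pair_id == "" & sm$has_methylation &
               sm$condition %in% c("diagnosis", "healthy", "remission"), ]
  proband <- trio$sample_id[trio$condition == "diagnosis"]
  twin <- trio$sample_id[trio$condition == "healthy"]
  remission <- trio$sample_id[trio$condition == "remission"]
  if (length(proband) != 1L || length(twin) != 1L || length(remission) != 1L)
    stop_input("sample sheet must contain exactly one unpaired diagnosis, healthy and remission methylation sample (the twin trio)")

  pair_frame <- function(flag_col) {
    paired <- sm[sm$pair_id != "" & sm[[flag_col]], ]
    ids <- sort(unique(paired$pair_id))
    ok <- vapply(ids, function(p) {
      sub <- paired[paired$pair_id == p, ]
      sum(sub$condition == "diagnosis") == 1L &&
        sum(sub$condition == "remission") == 1L
    }, logical(1))
    ids <- ids[ok]
    data.frame(
      diagnosis = vapply(ids, function(p)
        paired$sample_id[paired$pair_id == p & paired$condition == "diagnosis"], ""),
      remission = vapply(ids, function(p)
        paired$sample_id[paired$pair_id == p & paired$condition == "remission"], ""),
      stringsAsFactors = FALSE
    )
  }
  meth_pairs <- pair_frame("has_methylation")
  expr_pairs <- pair_frame("has_expression")
  both <- sm$has_methylation & sm$has_expression & sm$pair_id != ""
  dna_rna_samples <- sm$sample_id[both]

  list(
    proband = proband, twin = twin, remission = remission,
    parents = sm$sample_id[sm$condition == "parent"],
    meth_pairs = meth_pairs, expr_pairs = expr_pairs,
    dna_rna_samples = dna_rna_samples,
    meth_samples = sm$sample_id[sm$has_methylation],
    leukemic = sm$sample_id[sm$condition == "diagnosis" & sm$has_methylation],
    refs = sm$sample_id[sm$condition %in% c("ref_cd34", "ref_cd19")],
    adult_refs = sm$sample_id[sm$condition == "ref_cd19"]
  )
}

run_qc <- function(dataset, roles, top_probes, signature_cpgs, linkage,
                   parental_tolerance) {
  labels <- stats::setNames(
    ifelse(roles$meth_samples %in% roles$leukemic, "leukemic", "non-leukemic"),
    roles$meth_samples)
  qc <- list(distance = NULL, cluster = list(purity = NA_real_),
             pca = NULL, parental = NULL, labels = labels)
  if (length(top_probes) >= 2L) {
    qc$distance <- beta_distance_matrix(dataset$beta[top_probes, , drop = FALSE],
                                        roles$meth_samples)
    qc$cluster <- cluster_and_purity(qc$distance, labels, linkage = linkage)
    qc$pca <- pca_top_sites(dataset$beta, top_probes, roles$meth_samples)
  }
  if (length(signature_cpgs) && length(roles$parents)) {
    refs <- roles$adult_refs
    if (!length(refs))
      refs <- setdiff(roles$meth_samples,
                      c(roles$leukemic, roles$parents))
    qc$parental <- parental_check(signature_cpgs, dataset$beta,
                                  roles$parents, refs,
                                  tolerance = parental_tolerance)
  }
  qc
}

check_report_invariants <- function(r) {
  stopifnot(
    r$n_replicated <= r$n_twin_filtered,
    r$n_twin_hyper <= r$n_twin_filtered,
    r$n_replicated_hyper <= r$n_replicated,
    r$n_signature_genes <= r$n_overlap_genes,
    r$n_overlap_genes <= r$n_de_genes
  )
  invisible(r)
}

#' Write the stage tables and run report of a pipeline run
#'
#' Emits plain-text tables for every stage (`twin_filter.tsv`,
#' `replication.tsv`, `replicated.tsv`, `annotation.tsv`, `de.tsv`,
#' `correlation.tsv`, `signature.tsv`, `distance.tsv`) plus
#' `run_report.json`, sufficient to resume or audit any downstream stage.
#'
#' @param run a `twinmeth_run` object.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the directory.
#' @export
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_input("cannot create directory '%s'", out_dir)
  w <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(run$twin, "twin_filter.tsv")
  w(run$replication, "replication.tsv")
  w(run$replicated, "replicated.tsv")
  w(run$annotation, "annotation.tsv")
  w(run$de, "de.tsv")
  w(run$records, "correlation.tsv")
  w(run$signature, "signature.tsv")
  if (!is.null(run$qc$distance))
    utils::write.table(run$qc$distance, file.path(out_dir, "distance.tsv"),
                       sep = "\t", quote = FALSE)
  jsonlite::write_json(run$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(out_dir)
}

#' @export
print.twinmeth_run <- function(x, ...) {
  r <- x$report
  cat("Twin methylome-transcriptome integration run\n")
  cat(sprintf("  probes: %d -> twin-filtered %d (%d hyper) -> replicated %d (%d hyper)\n",
              r$n_probes_input, r$n_twin_filtered, r$n_twin_hyper,
              r$n_replicated, r$n_replicated_hyper))
  cat(sprintf("  genes: %d annotated; %d differentially expressed (%d up / %d down); %d overlap\n",
              r$n_genes_annotated, r$n_de_genes, r$n_de_up, r$n_de_down,
              r$n_overlap_genes))
  cat(sprintf("  signature: %d genes, %d CpGs (promoter fraction %s)\n",
              r$n_signature_genes, r$n_signature_cpgs,
              ifelse(is.na(r$promoter_fraction), "NA",
                     sprintf("%.2f", r$promoter_fraction))))
  cat(sprintf("  QC: first-split purity %s; parents comparable at %s of signature CpGs\n",
              ifelse(is.na(r$cluster_purity), "NA",
                     sprintf("%.2f", r$cluster_purity)),
              ifelse(is.na(r$parental_fraction_comparable), "NA",
                     sprintf("%.2f", r$parental_fraction_comparable))))
  invisible(x)
}

#' @export
summary.twinmeth_run <- function(object, ...) {
  print(object)
  if (nrow(object$signature)) {
    cat("\nSignature genes (sorted by DE FDR):\n")
    print(object$signature, row.names = FALSE)
  } else {
    cat("\nNo signature genes reported.\n")
  }
  invisible(object$report)
}

#' @export
plot.twinmeth_run <- function(x, components = c(1, 2), ...) {
  if (is.null(x$qc$pca) || x$qc$pca$degenerate)
    stop_input("no non-degenerate PCA available in this run")
  sc <- x$qc$pca$scores[, components, drop = FALSE]
  labs <- x$qc$labels[rownames(sc)]
  ev <- round(100 * x$qc$pca$explained_variance_fraction[components], 1)
  graphics::plot(sc[, 1], sc[, 2],
                 col = ifelse(labs == "leukemic", 2, 4),
                 pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1], ev[1]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2], ev[2]),
                 main = "Targeted PCA of replicated CpGs", ...)
  graphics::text(sc[, 1], sc[, 2], rownames(sc), pos = 3, cex = 0.7)
  graphics::legend("topright", legend = c("leukemic", "non-leukemic"),
                   col = c(2, 4), pch = 19, bty = "n")
  invisible(x)
}

#' Per-gene diagnosis-vs-remission panels
#'
#' For each signature gene, assembles the data behind a per-gene figure:
#' normalized log2 expression across the paired samples, the beta values of
#' the gene's signature CpGs across the same samples, and the per-CpG rho and
#' adjusted correlation p.
#'
#' @param run a `twinmeth_run`.
#' @param beta the beta matrix the run was computed from.
#' @param genes genes to summarize (default: all signature genes).
#' @return named list, one element per gene: list with `panel` (first row the
#'   expression values, then one row per CpG) and `correlations`.
#' @export
gene_panels <- function(run, beta, genes = NULL) {
  if (is.null(genes)) genes <- run$signature$gene
  if (length(genes) == 0L) {
    message("no signature genes to summarize")
    return(list())
  }
  samples <- run$roles$dna_rna_samples
  out <- list()
  for (g in genes) {
    if (!g %in% rownames(run$norm_expr))
      stop_input("gene '%s' is absent from the expression matrix", g)
    i <- match(g, run$signature$gene)
    if (is.na(i))
      stop_input("gene '%s' is not a signature gene in this run", g)
    cpgs <- strsplit(run$signature$cpgs[i], ";", fixed = TRUE)[[1]]
    panel <- rbind(
      expression = run$norm_expr[g, samples],
      beta[cpgs, samples, drop = FALSE]
    )
    rec <- run$records[run$records$gene == g &
                         run$records$probe_id %in% cpgs,
                       c("probe_id", "rho", "p_corr")]
    out[[g]] <- list(panel = panel, correlations = rec)
  }
  out
}

#' Score a pipeline run against the generator's ground truth
#'
#' Computes the recovery metrics used throughout the test suite: signature
#' gene sensitivity and false-reporting rate, the recovered hypermethylated
#' fraction of the replicated set, correlation-sign agreement, twin-filter
#' probe sensitivity / null retention, and the composition-probe depletion
#' ratio between the replicated set and the final signature CpGs.
#'
#' @param run a `twinmeth_run`.
#' @param truth the generator truth table (defaults to the one stored in the
#'   run, if the dataset carried it).
#' @return named list of metrics.
#' @export
evaluate_run <- function(run, truth = run$truth) {
  if (is.null(truth))
    stop_input("no truth table available")
  tp <- truth$probes
  tg <- truth$genes
  sig_genes <- tg$gene[tg$is_signature]
  found <- run$signature$gene
  sens <- if (length(sig_genes)) mean(sig_genes %in% found) else NA_real_
  false_frac <- if (length(found)) mean(!found %in% sig_genes) else 0

  rep_probes <- run$replicated$probe_id
  hyper_frac <- if (length(rep_probes))
    mean(run$replicated$direction == "hyper") else NA_real_

  common <- intersect(found, sig_genes)
  sign_ok <- if (length(common)) {
    truth_sign <- tg$correlation_sign[match(common, tg$gene)]
    got_sign <- run$signature$correlation_sign[match(common, found)]
    mean(truth_sign == got_sign)
  } else NA_real_

  twin_ret <- run$twin$probe_id[run$twin$retained]
  sig_probes <- tp$probe_id[tp$is_signature]
  null_probes <- tp$probe_id[!tp$is_signature & !tp$is_composition_confounded]
  probe_sens <- if (length(sig_probes)) mean(sig_probes %in% twin_ret) else NA_real_
  null_ret <- mean(null_probes %in% twin_ret)

  comp_probes <- tp$probe_id[tp$is_composition_confounded]
  comp_rep <- mean(comp_probes %in% rep_probes)
  sig_rep <- mean(sig_probes %in% rep_probes)
  comp_sig <- mean(comp_probes %in% run$signature_cpgs)
  sig_sig <- mean(sig_probes %in% run$signature_cpgs)
  # depletion of composition probes relative to signature probes going from
  # the replicated set to the final signature CpGs
  depletion <- (comp_rep / max(sig_rep, 1e-12)) /
    max(comp_sig / max(sig_sig, 1e-12), 1e-12)

  list(
    gene_sensitivity = sens,
    false_gene_fraction = false_frac,
    replicated_hyper_fraction = hyper_frac,
    sign_agreement = sign_ok,
    twin_probe_sensitivity = probe_sens,
    twin_null_retention = null_ret,
    composition_replication_rate = comp_rep,
    composition_signature_rate = comp_sig,
    composition_depletion = depletion
  )
}
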