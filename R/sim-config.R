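#' Configuration for the synthetic twin-leukemia dataset
#'
#' Builds and validates the parameter set used by [generate_manifest()],
#' [simulate_methylation()] and [simulate_counts()]. The defaults describe the
#' study design the package models: a discordant monozygotic twin trio
#' (proband at diagnosis, healthy twin, proband at remission) with both
#' parents, three independent diagnosis-remission pairs assayed for both DNA
#' methylation and RNA, one extra pair with RNA only, and CD34+/CD19+
#' reference-cell methylomes. Planted effects mirror the magnitudes seen in
#' KMT2A/AFF1 infant ALL: large delta-beta shifts (0.45 by default, within the
#' 0.3-0.85 range the twin filter targets), predominantly hypermethylated
#' (85.5%), strong expression fold changes (|log2FC| = 6) and tight
#' methylation-expression coupling (target |rho| = 0.9).
#'
#' @param n_probes total number of CpG probes on the simulated array.
#' @param n_genes total number of genes with expression counts.
#' @param n_signature_genes genes carrying the planted methylation-expression
#'   signature.
#' @param cpgs_per_signature_gene planted CpGs per signature gene (>= 3 so the
#'   signature rule can recover them).
#' @param n_pairs diagnosis-remission pairs with both assays.
#' @param n_expr_only_pairs extra pairs with expression only (no methylation).
#' @param planted_delta_beta absolute beta shift planted at signature probes in
#'   diagnosis samples; must be >= 0.3 or the planted truth could not pass the
#'   twin filter.
#' @param hyper_fraction fraction of signature genes (and composition probes)
#'   planted as hypermethylated at diagnosis; applied as an exact quota.
#' @param n_composition_probes probes carrying a cell-composition offset shared
#'   by all diagnosis-condition samples and the reference cells. These confound
#'   the diagnosis contrast but are not disease truth.
#' @param beta_precision precision of the beta distribution used for per-sample
#'   noise (variance = m(1-m)/(1+precision); larger is less noisy).
#' @param nb_dispersion negative-binomial dispersion of the count model.
#' @param planted_abs_log2fc absolute log2 fold change (diagnosis vs remission)
#'   planted at signature genes and methylation-independent DE genes.
#' @param target_abs_rho target absolute Pearson correlation between signature
#'   CpG beta and log2 expression over the paired samples; calibrates the
#'   expression noise (must be in (0.7, 1]).
#' @param positive_correlation_gene_fraction fraction of signature genes whose
#'   methylation-expression link is positive (the MACROD2-like exception);
#'   applied as an exact quota, the rest are negative.
#' @param n_de_genes methylation-independent differentially expressed genes
#'   planted so the expression stage has positives outside the signature.
#' @param planted_log10_mean_min lower bound (log10) of the base expression of
#'   planted (signature and DE) genes; background genes span 10^0.5 to 10^3.5.
#'   Planted genes sit in the reliably expressed range so the planted fold
#'   change is identifiable above the count-noise floor.
#' @param promoter_fraction fraction of signature probes assigned promoter
#'   (TSS1500/TSS200) regions.
#' @param multi_gene_fraction fraction of annotated probes carrying a second
#'   gene annotation.
#' @param annotated_fraction fraction of background probes annotated to a gene
#'   at all.
#' @param missing_rate fraction of beta values set missing at random.
#' @param seed integer seed; the full dataset is bit-reproducible given it.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 20000L,
                       n_genes = 2000L,
                       n_signature_genes = 30L,
                       cpgs_per_signature_gene = 4L,
                       n_pairs = 3L,
                       n_expr_only_pairs = 1L,
                       planted_delta_beta = 0.45,
                       hyper_fraction = 0.855,
                       n_composition_probes = 60L,
                       beta_precision = 300,
                       nb_dispersion = 0.05,
                       planted_abs_log2fc = 6,
                       target_abs_rho = 0.9,
                       positive_correlation_gene_fraction = 0.1,
                       n_de_genes = 150L,
                       planted_log10_mean_min = 1.5,
                       promoter_fraction = 0.65,
                       multi_gene_fraction = 0.05,
                       annotated_fraction = 0.75,
                       missing_rate = 0.002,
                       seed = 1L) {
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    cpgs_per_signature_gene = as.integer(cpgs_per_signature_gene),
    n_pairs = as.integer(n_pairs),
    n_expr_only_pairs = as.integer(n_expr_only_pairs),
    planted_delta_beta = planted_delta_beta,
    hyper_fraction = hyper_fraction,
    n_composition_probes = as.integer(n_composition_probes),
    beta_precision = beta_precision,
    nb_dispersion = nb_dispersion,
    planted_abs_log2fc = planted_abs_log2fc,
    target_abs_rho = target_abs_rho,
    positive_correlation_gene_fraction = positive_correlation_gene_fraction,
    n_de_genes = as.integer(n_de_genes),
    planted_log10_mean_min = planted_log10_mean_min,
    promoter_fraction = promoter_fraction,
    multi_gene_fraction = multi_gene_fraction,
    annotated_fraction = annotated_fraction,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

config_error <- function(field, why) {
  stop_input("invalid simulation configuration: field '%s' %s", field, why)
}

validate_sim_config <- function(cfg) {
  pos_count <- function(field) {
    if (is.na(cfg[[field]]) || cfg[[field]] <= 0L)
      config_error(field, "must be a positive count")
  }
  for (f in c("n_probes", "n_genes", "n_pairs", "seed"))
    if (is.na(cfg[[f]])) config_error(f, "must be an integer")
  pos_count("n_probes")
  pos_count("n_genes")
  pos_count("n_pairs")
  if (cfg$n_signature_genes < 0L) config_error("n_signature_genes", "must be >= 0")
  if (cfg$n_expr_only_pairs < 0L) config_error("n_expr_only_pairs", "must be >= 0")
  if (cfg$n_composition_probes < 0L) config_error("n_composition_probes", "must be >= 0")
  if (cfg$n_de_genes < 0L) config_error("n_de_genes", "must be >= 0")
  if (cfg$n_signature_genes > 0L && cfg$cpgs_per_signature_gene < 3L)
    config_error("cpgs_per_signature_gene", "must be >= 3")
  if (cfg$n_signature_genes * cfg$cpgs_per_signature_gene > cfg$n_probes)
    config_error("n_probes",
                 "must be >= n_signature_genes * cpgs_per_signature_gene")
  if (cfg$n_signature_genes + cfg$n_de_genes > cfg$n_genes)
    config_error("n_genes", "must cover signature plus planted DE genes")
  if (cfg$planted_delta_beta < 0.3 || cfg$planted_delta_beta > 0.85)
    config_error("planted_delta_beta", "must lie in [0.3, 0.85]")
  for (f in c("hyper_fraction", "positive_correlation_gene_fraction",
              "promoter_fraction", "multi_gene_fraction",
              "annotated_fraction", "missing_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) config_error(f, "must lie in [0, 1]")
  }
  if (cfg$beta_precision <= 0) config_error("beta_precision", "must be > 0")
  if (cfg$nb_dispersion <= 0) config_error("nb_dispersion", "must be > 0")
  if (cfg$planted_abs_log2fc < 0) config_error("planted_abs_log2fc", "must be >= 0")
  if (cfg$target_abs_rho <= 0.7 || cfg$target_abs_rho > 1)
    config_error("target_abs_rho", "must lie in (0.7, 1]")
  if (cfg$planted_log10_mean_min < 0.5 || cfg$planted_log10_mean_min >= 3.5)
    config_error("planted_log10_mean_min", "must lie in [0.5, 3.5)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic twin-ALL dataset configuration\n")
  cat(sprintf("  probes: %d (%d signature CpGs on %d genes, %d composition-confounded)\n",
              x$n_probes, x$n_signature_genes * x$cpgs_per_signature_gene,
              x$n_signature_genes, x$n_composition_probes))
  cat(sprintf("  genes: %d (%d methylation-independent DE)\n", x$n_genes, x$n_de_genes))
  cat(sprintf("  pairs: %d with DNA+RNA, %d RNA-only\n", x$n_pairs, x$n_expr_only_pairs))
  cat(sprintf("  planted: |delta beta| %.2f (hyper quota %.3f), |log2FC| %.1f, target |rho| %.2f\n",
              x$planted_delta_beta, x$hyper_fraction, x$planted_abs_log2fc, x$target_abs_rho))
  cat(sprintf("  noise: beta precision %.0f, NB dispersion %.3f; seed %d\n",
              x$beta_precision, x$nb_dispersion, x$seed))
  invisible(x)
}
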