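#' Simulate gene-level RNA counts linked to the planted methylation
#'
#' Counts are negative binomial with gene base means spanning about three
#' orders of magnitude and dispersion `nb_dispersion`. Signature genes follow
#' a deterministic methylation-to-expression link: each expression sample's
#' log2 mean is offset by `slope * (mean signature-probe beta - baseline)`,
#' with slope `+/- planted_abs_log2fc / planted_delta_beta` (negative for
#' negatively correlated genes, positive for the MACROD2-like exceptions), so
#' the realized diagnosis-vs-remission log2 fold change matches the planted
#' truth and per-CpG Pearson correlations carry the planted sign. A small
#' link-noise term, sd `(1 - target_abs_rho) * planted_abs_log2fc / 2` log2
#' units, bounds the coupling away from exactly 1 while keeping realized
#' |rho| at or above the target. Methylation-independent DE genes get their
#' planted log2 fold change directly; expression-only pairs use a latent
#' methylation draw for signature genes.
#'
#' @param config a [sim_config()] object.
#' @param truth the truth table from [simulate_methylation()].
#' @param beta the beta matrix from [simulate_methylation()].
#' @param samples the sample sheet from [simulate_methylation()].
#' @return an integer matrix of counts, genes x expression samples.
#' @export
simulate_counts <- function(config, truth, beta, samples) {
  validate_sim_config(config)
  expr_samples <- samples$sample_id[samples$has_expression]
  n_expected <- 2L * (config$n_pairs + config$n_expr_only_pairs)
  if (length(expr_samples) < n_expected)
    stop_input("expression samples missing: expected %d, found %d",
               n_expected, length(expr_samples))
  set.seed(config$seed + 2L)

  tg <- truth$genes
  tp <- truth$probes
  n_genes <- nrow(tg)
  special <- tg$is_signature | tg$is_de_planted

  base_mean <- numeric(n_genes)
  # planted genes sit in the reliably expressed range; background spans wider
  base_mean[!special] <- 10^stats::runif(sum(!special), 0.5, 3.5)
  base_mean[special] <- 10^stats::runif(sum(special),
                                        config$planted_log10_mean_min, 3.5)
  lib <- exp(stats::rnorm(length(expr_samples), 0, 0.15))

  cond <- stats::setNames(samples$condition, samples$sample_id)[expr_samples]
  has_meth <- stats::setNames(samples$has_methylation, samples$sample_id)[expr_samples]
  is_diag <- cond == "diagnosis"

  offset <- matrix(0, n_genes, length(expr_samples),
                   dimnames = list(tg$gene, expr_samples))

  de_rows <- which(tg$is_de_planted)
  if (length(de_rows) && any(is_diag))
    offset[de_rows, is_diag] <- tg$true_log2fc[de_rows]

  sig_rows <- which(tg$is_signature)
  sd_link <- (1 - config$target_abs_rho) * config$planted_abs_log2fc / 2
  for (g in sig_rows) {
    gene <- tg$gene[g]
    probes <- tp$probe_id[tp$is_signature & !is.na(tp$gene) & tp$gene == gene]
    b0 <- mean(tp$baseline[match(probes, tp$probe_id)])
    link_sign <- if (tg$correlation_sign[g] == "+") 1 else -1
    slope <- link_sign * config$planted_abs_log2fc / config$planted_delta_beta
    for (j in seq_along(expr_samples)) {
      s <- expr_samples[j]
      if (has_meth[j] && s %in% colnames(beta)) {
        mb <- mean(beta[probes, s], na.rm = TRUE)
        if (is.nan(mb)) mb <- b0 + if (is_diag[j]) tp$planted_shift[match(probes[1], tp$probe_id)] else 0
      } else {
        # latent methylation for expression-only pairs
        mb <- b0 + (if (is_diag[j]) tp$planted_shift[match(probes[1], tp$probe_id)] else 0) +
          stats::rnorm(1, 0, 0.015)
      }
      offset[g, j] <- slope * (mb - b0)
    }
    if (sd_link > 0)
      offset[g, ] <- offset[g, ] + stats::rnorm(length(expr_samples), 0, sd_link)
  }

  mu <- base_mean * t(t(2^offset) * lib)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
    nrow = n_genes, dimnames = dimnames(offset)
  )
  storage.mode(counts) <- "integer"
  counts
}

#' Generate a complete synthetic twin-leukemia dataset
#'
#' Convenience wrapper running [generate_manifest()],
#' [simulate_methylation()] and [simulate_counts()] in sequence. With a fixed
#' seed the full dataset is bit-reproducible.
#'
#' @param config a [sim_config()] object (or a list of its arguments).
#' @return an object of class `twinmeth_sim`: list with `config`, `manifest`
#'   (450K-dialect data.frame), `beta`, `samples`, `counts` and `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  man <- generate_manifest(config)
  meth <- simulate_methylation(config, man)
  counts <- simulate_counts(config, meth$truth, meth$beta, meth$samples)
  structure(
    list(config = config, manifest = man$manifest, beta = meth$beta,
         samples = meth$samples, counts = counts, truth = meth$truth),
    class = "twinmeth_sim"
  )
}

#' @export
print.twinmeth_sim <- function(x, ...) {
  cat(sprintf("Synthetic twin-ALL dataset: %d probes x %d methylation samples; %d genes x %d expression samples\n",
              nrow(x$beta), ncol(x$beta), nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  planted: %d signature CpGs on %d genes, %d composition-confounded probes, %d DE-only genes (seed %d)\n",
              sum(x$truth$probes$is_signature), sum(x$truth$genes$is_signature),
              sum(x$truth$probes$is_composition_confounded),
              sum(x$truth$genes$is_de_planted), x$config$seed))
  invisible(x)
}
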