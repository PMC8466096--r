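#' Simulate the methylation beta matrix, sample sheet and truth table
#'
#' Draws per-probe baseline methylation from a bimodal mixture (low/high
#' modes plus a minor intermediate mode, as on real arrays) and per-sample
#' beta values from a beta distribution with that baseline mean and precision
#' `beta_precision`. Signature probes are shifted by `planted_delta_beta` in
#' diagnosis-condition samples only, with direction (hyper/hypo) assigned per
#' gene by an exact `hyper_fraction` quota. Composition-confounded probes are
#' shifted in all diagnosis-condition samples and in the reference CD34+/CD19+
#' profiles (CD19 at a reduced scale, mimicking a distinct mature cell type);
#' they confound the diagnosis contrast but are not disease truth. The twin
#' and the remission sample of the trio share the healthy baseline up to
#' noise. Values are clipped to [0.001, 0.999] and rounded to 6 decimals so a
#' text round trip is exact.
#'
#' @param config a [sim_config()] object.
#' @param manifest a `cpg_manifest` from [generate_manifest()].
#' @return a list with elements `beta` (probes x samples matrix, in [0,1],
#'   with missing values), `samples` (the sample sheet data.frame) and `truth`
#'   (list of `probes` and `genes` data.frames with planted effects).
#' @export
simulate_methylation <- function(config, manifest) {
  if (!inherits(manifest, "cpg_manifest"))
    stop_input("'manifest' must come from generate_manifest()")
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  tp <- manifest$truth_probes
  tg <- manifest$truth_genes
  n <- nrow(tp)
  sig_genes <- tg$gene[tg$is_signature]
  n_sig_genes <- length(sig_genes)

  # directions: exact quota of hypermethylated genes / composition probes
  gene_dir <- character(0)
  if (n_sig_genes > 0L) {
    n_hyper <- round(config$hyper_fraction * n_sig_genes)
    ord <- sample(sig_genes)
    gene_dir <- stats::setNames(
      c(rep("hyper", n_hyper), rep("hypo", n_sig_genes - n_hyper))[match(sig_genes, ord)],
      sig_genes
    )
  }
  probe_dir <- rep(NA_character_, n)
  sig_rows <- which(tp$is_signature)
  if (length(sig_rows)) probe_dir[sig_rows] <- gene_dir[tp$gene[sig_rows]]
  comp_rows <- which(tp$is_composition_confounded)
  if (length(comp_rows)) {
    n_hyper_c <- round(config$hyper_fraction * length(comp_rows))
    dir_c <- sample(c(rep("hyper", n_hyper_c),
                      rep("hypo", length(comp_rows) - n_hyper_c)))
    probe_dir[comp_rows] <- dir_c
  }

  # baselines: shifted probes start where the planted shift fits inside (0,1)
  baseline <- numeric(n)
  mode <- sample(c("low", "mid", "high"), n, replace = TRUE,
                 prob = c(0.42, 0.16, 0.42))
  baseline[mode == "low"] <- stats::rbeta(sum(mode == "low"), 2, 20)
  baseline[mode == "mid"] <- stats::rbeta(sum(mode == "mid"), 5, 5)
  baseline[mode == "high"] <- stats::rbeta(sum(mode == "high"), 20, 2)
  shifted <- c(sig_rows, comp_rows)
  if (length(shifted)) {
    hyper <- shifted[probe_dir[shifted] == "hyper"]
    hypo <- shifted[probe_dir[shifted] == "hypo"]
    baseline[hyper] <- stats::runif(length(hyper), 0.10, min(0.35, 0.99 - config$planted_delta_beta))
    baseline[hypo] <- stats::runif(length(hypo), max(0.65, 0.01 + config$planted_delta_beta), 0.90)
  }

  # planted per-probe shift (signed)
  shift <- rep(0, n)
  if (length(sig_rows))
    shift[sig_rows] <- ifelse(probe_dir[sig_rows] == "hyper", 1, -1) * config$planted_delta_beta
  if (length(comp_rows))
    shift[comp_rows] <- ifelse(probe_dir[comp_rows] == "hyper", 1, -1) *
      stats::runif(length(comp_rows), 0.35, 0.55)

  samples <- build_sample_sheet(config)
  meth_samples <- samples$sample_id[samples$has_methylation]
  cond <- stats::setNames(samples$condition, samples$sample_id)[meth_samples]

  means <- matrix(baseline, nrow = n, ncol = length(meth_samples),
                  dimnames = list(tp$probe_id, meth_samples))
  is_diag <- cond == "diagnosis"
  if (length(sig_rows) && any(is_diag))
    means[sig_rows, is_diag] <- means[sig_rows, is_diag] + shift[sig_rows]
  if (length(comp_rows)) {
    comp_scale <- ifelse(cond == "diagnosis", 1,
                  ifelse(cond == "ref_cd34", 1,
                  ifelse(cond == "ref_cd19", 0.6, 0)))
    nonzero <- which(comp_scale > 0)
    for (j in nonzero)
      means[comp_rows, j] <- means[comp_rows, j] + shift[comp_rows] * comp_scale[j]
  }
  out_of_range <- means <= 0 | means >= 1
  if (any(out_of_range))
    warning(sprintf("%d planted means fell outside (0,1) and were clipped",
                    sum(out_of_range)))
  means <- pmin(pmax(means, 0.001), 0.999)

  phi <- config$beta_precision
  beta <- matrix(
    stats::rbeta(length(means), means * phi, (1 - means) * phi),
    nrow = n, dimnames = dimnames(means)
  )
  beta <- round(pmin(pmax(beta, 0.001), 0.999), 6)
  if (config$missing_rate > 0) {
    nas <- which(stats::runif(length(beta)) < config$missing_rate)
    beta[nas] <- NA_real_
  }

  # gene-level truth: correlation sign quota and planted log2 fold changes
  tg$correlation_sign <- NA_character_
  tg$direction <- NA_character_
  tg$true_log2fc <- 0
  if (n_sig_genes > 0L) {
    n_pos <- round(config$positive_correlation_gene_fraction * n_sig_genes)
    pos_genes <- sample(sig_genes, n_pos)
    i <- match(sig_genes, tg$gene)
    tg$correlation_sign[i] <- ifelse(sig_genes %in% pos_genes, "+", "-")
    tg$direction[i] <- gene_dir[sig_genes]
    dir_sign <- ifelse(gene_dir[sig_genes] == "hyper", 1, -1)
    link_sign <- ifelse(sig_genes %in% pos_genes, 1, -1)
    tg$true_log2fc[i] <- link_sign * dir_sign * config$planted_abs_log2fc
  }
  de_rows <- which(tg$is_de_planted)
  if (length(de_rows))
    tg$true_log2fc[de_rows] <- sample(c(-1, 1), length(de_rows), replace = TRUE) *
      stats::runif(length(de_rows), 2, max(2.5, config$planted_abs_log2fc))

  tp$direction <- probe_dir
  tp$baseline <- round(baseline, 6)
  tp$planted_shift <- round(shift, 6)

  list(beta = beta, samples = samples, truth = list(probes = tp, genes = tg))
}

# sample sheet of the emulated study: twin trio + parents, diagnosis-remission
# pairs (DNA+RNA), expression-only pairs, and >=3 reference profiles per cell
# type.
build_sample_sheet <- function(config) {
  rows <- list(
    c("S1", "PROBAND", "diagnosis", "", TRUE, FALSE),
    c("S2", "TWIN", "healthy", "", TRUE, FALSE),
    c("S3", "PROBAND", "remission", "", TRUE, FALSE),
    c("S4", "MOTHER", "parent", "", TRUE, FALSE),
    c("S5", "FATHER", "parent", "", TRUE, FALSE)
  )
  for (i in seq_len(config$n_pairs)) {
    id <- sprintf("A%d", i)
    rows <- c(rows, list(
      c(sprintf("%s_d", id), id, "diagnosis", id, TRUE, TRUE),
      c(sprintf("%s_r", id), id, "remission", id, TRUE, TRUE)
    ))
  }
  for (j in seq_len(config$n_expr_only_pairs)) {
    id <- sprintf("A%d", config$n_pairs + j)
    rows <- c(rows, list(
      c(sprintf("%s_d", id), id, "diagnosis", id, FALSE, TRUE),
      c(sprintf("%s_r", id), id, "remission", id, FALSE, TRUE)
    ))
  }
  for (k in 1:3) {
    rows <- c(rows, list(
      c(sprintf("CD34_%d", k), sprintf("REFCD34_%d", k), "ref_cd34", "", TRUE, FALSE)
    ))
  }
  for (k in 1:3) {
    rows <- c(rows, list(
      c(sprintf("CD19_%d", k), sprintf("REFCD19_%d", k), "ref_cd19", "", TRUE, FALSE)
    ))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "subject_id", "condition", "pair_id",
                 "has_methylation", "has_expression")
  df$has_methylation <- df$has_methylation == "TRUE"
  df$has_expression <- df$has_expression == "TRUE"
  df
}
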