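test_that("configuration invariants are enforced with the field named", {
  expect_error(sim_config(n_probes = 0), "n_probes")
  expect_error(sim_config(planted_delta_beta = 0.2), "planted_delta_beta")
  expect_error(sim_config(hyper_fraction = 1.2), "hyper_fraction")
  expect_error(sim_config(cpgs_per_signature_gene = 2), "cpgs_per_signature_gene")
  expect_error(sim_config(n_probes = 10, n_signature_genes = 5,
                          n_genes = 50, n_de_genes = 0), "n_probes")
  expect_error(sim_config(target_abs_rho = 0.5), "target_abs_rho")
})

test_that("the manifest plants exactly the configured signature probes", {
  cfg <- small_config(n_signature_genes = 5, cpgs_per_signature_gene = 3)
  man <- generate_manifest(cfg)
  expect_equal(sum(man$truth_probes$is_signature), 15L)
  # every signature gene has exactly cpgs_per_signature_gene probes
  sig <- man$truth_probes[man$truth_probes$is_signature, ]
  expect_true(all(table(sig$gene) == 3L))
  expect_equal(sum(man$truth_genes$is_signature), 5L)
})

test_that("manifest generation is deterministic and positions increase per chromosome", {
  cfg <- small_config(seed = 9)
  a <- generate_manifest(cfg)
  b <- generate_manifest(cfg)
  expect_identical(a, b)
  for (chr in unique(a$manifest$CHR)) {
    pos <- a$manifest$MAPINFO[a$manifest$CHR == chr]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos >= 1))
  }
  regions <- unlist(strsplit(a$manifest$UCSC_RefGene_Group, ";"))
  expect_true(all(regions %in% c("", "TSS1500", "TSS200", "5'UTR",
                                 "1stExon", "Body", "3'UTR")))
  # some probes carry multi-gene annotations, some none
  expect_gt(sum(grepl(";", a$manifest$UCSC_RefGene_Name)), 0)
  expect_gt(sum(a$manifest$UCSC_RefGene_Name == ""), 0)
})

test_that("composition-confounded probes are never signature probes and avoid DE genes", {
  man <- generate_manifest(small_config())
  tp <- man$truth_probes
  expect_false(any(tp$is_signature & tp$is_composition_confounded))
  comp_genes <- unique(tp$gene[tp$is_composition_confounded])
  tg <- man$truth_genes
  expect_false(any(comp_genes %in% tg$gene[tg$is_de_planted]))
  expect_false(any(comp_genes %in% tg$gene[tg$is_signature]))
})

test_that("a near-noise-free simulation recovers the planted delta beta", {
  cfg <- small_config(beta_precision = 1e6, planted_delta_beta = 0.4,
                      missing_rate = 0, seed = 5)
  man <- generate_manifest(cfg)
  sim <- simulate_methylation(cfg, man)
  sm <- sim$samples
  diag <- sm$sample_id[sm$condition == "diagnosis" & sm$has_methylation]
  rem <- sm$sample_id[sm$condition == "remission" & sm$has_methylation]
  sig <- sim$truth$probes$probe_id[sim$truth$probes$is_signature]
  gap <- abs(rowMeans(sim$beta[sig, diag, drop = FALSE]) -
               rowMeans(sim$beta[sig, rem, drop = FALSE]))
  expect_true(all(abs(gap - 0.4) <= 0.02))
})

test_that("hyper_fraction 1 plants only hypermethylation", {
  cfg <- small_config(hyper_fraction = 1, seed = 6)
  sim <- simulate_methylation(cfg, generate_manifest(cfg))
  tp <- sim$truth$probes
  expect_true(all(tp$direction[tp$is_signature] == "hyper"))
})

test_that("planted twin contrasts pass the delta-beta filter at high rate", {
  hits <- sapply(1:5, function(s) {
    cfg <- sim_config(seed = s)
    sim <- simulate_methylation(cfg, generate_manifest(cfg))
    tp <- sim$truth$probes
    sig <- tp$probe_id[tp$is_signature]
    b <- sim$beta[sig, c("S1", "S2"), drop = FALSE]
    mean(abs(b[, "S1"] - b[, "S2"]) >= 0.3, na.rm = TRUE)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("beta values are valid and the full dataset is bit-reproducible", {
  cfg <- small_config(seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  expect_true(all(is.na(a$beta) | (a$beta >= 0.001 & a$beta <= 0.999)))
  expect_gt(sum(is.na(a$beta)), 0)
  expect_true(all(a$counts >= 0))
})

test_that("the noise-free count limit recovers the planted log2 fold change", {
  # dispersion -> 0 and a deterministic link; the Poisson sampling floor
  # remains, so planted genes sit at high expression and the tight bound is
  # checked on the per-gene average
  cfg <- small_config(nb_dispersion = 1e-4, target_abs_rho = 1,
                      planted_abs_log2fc = 6, planted_log10_mean_min = 3.2,
                      n_signature_genes = 20, n_pairs = 6,
                      n_expr_only_pairs = 0, missing_rate = 0, seed = 12)
  ds <- simulate_dataset(cfg)
  norm <- normalize_log2(ds$counts, size_factors(ds$counts))
  sm <- ds$samples
  diag <- sm$sample_id[sm$has_expression & sm$condition == "diagnosis"]
  rem <- sm$sample_id[sm$has_expression & sm$condition == "remission"]
  tg <- ds$truth$genes
  sig <- tg[tg$is_signature, ]
  l2fc <- rowMeans(norm[sig$gene, diag, drop = FALSE]) -
    rowMeans(norm[sig$gene, rem, drop = FALSE])
  expect_true(all(sign(l2fc) == sign(sig$true_log2fc)))
  expect_gte(mean(abs(l2fc - sig$true_log2fc) <= 0.5), 0.9)
  expect_lte(abs(mean(abs(l2fc)) - 6), 0.2)
})

test_that("the methylation-expression link carries the planted sign", {
  cfg <- small_config(nb_dispersion = 1e-4, target_abs_rho = 1,
                      missing_rate = 0, seed = 13)
  ds <- simulate_dataset(cfg)
  norm <- normalize_log2(ds$counts, size_factors(ds$counts))
  sm <- ds$samples
  both <- sm$sample_id[sm$has_methylation & sm$has_expression]
  tg <- ds$truth$genes
  tp <- ds$truth$probes
  for (g in tg$gene[tg$is_signature]) {
    probes <- tp$probe_id[tp$is_signature & !is.na(tp$gene) & tp$gene == g]
    rho <- cor(ds$beta[probes[1], both], norm[g, both])
    want <- tg$correlation_sign[tg$gene == g]
    expect_equal(if (rho > 0) "+" else "-", want)
  }
})

test_that("most signature CpGs reach |rho| >= 0.7 on the DNA+RNA samples", {
  ds <- simulate_dataset(sim_config(seed = 7))
  norm <- normalize_log2(ds$counts, size_factors(ds$counts))
  sm <- ds$samples
  both <- sm$sample_id[sm$has_methylation & sm$has_expression]
  tp <- ds$truth$probes
  sig <- tp[tp$is_signature, ]
  rhos <- vapply(seq_len(nrow(sig)), function(i) {
    x <- ds$beta[sig$probe_id[i], both]
    y <- norm[sig$gene[i], both]
    ok <- !is.na(x) & !is.na(y)
    cor(x[ok], y[ok])
  }, numeric(1))
  expect_gte(mean(abs(rhos) >= 0.7), 0.8)
})

test_that("counts require the expression samples to be present", {
  cfg <- small_config(seed = 14)
  man <- generate_manifest(cfg)
  sim <- simulate_methylation(cfg, man)
  truncated <- sim$samples[sim$samples$condition != "diagnosis" |
                             !sim$samples$has_expression, ]
  expect_error(simulate_counts(cfg, sim$truth, sim$beta, truncated),
               "expression samples missing")
})
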