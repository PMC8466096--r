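cor_fixture <- function(beta_vals, expr_vals, probe = "cg1", gene = "G1") {
  samples <- sprintf("s%d", seq_along(beta_vals))
  beta <- matrix(beta_vals, 1, dimnames = list(probe, samples))
  expr <- matrix(expr_vals, 1, dimnames = list(gene, samples))
  list(beta = beta, expr = expr, samples = samples,
       cand = data.frame(probe_id = probe, gene = gene,
                         stringsAsFactors = FALSE))
}

test_that("Pearson rho matches the direct formula on the worked vectors", {
  f <- cor_fixture(c(0.8, 0.75, 0.7, 0.3, 0.25, 0.2), c(1, 2, 3, 8, 9, 10))
  rec <- correlate_cpg_gene(f$beta, f$expr, f$cand, f$samples)
  expect_equal(round(rec$rho, 4), -0.9977)
  expect_equal(rec$rho, oracle_pearson(f$beta[1, ], f$expr[1, ]),
               tolerance = 1e-12)
  expect_equal(rec$n_samples, 6L)
})

test_that("an exact decreasing linear function gives rho = -1", {
  b <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  f <- cor_fixture(b, 10 - 5 * b)
  rec <- correlate_cpg_gene(f$beta, f$expr, f$cand, f$samples)
  expect_equal(rec$rho, -1)
  expect_equal(rec$p_value, 0)
})

test_that("constant vectors are flagged degenerate and not tested", {
  f <- cor_fixture(rep(0.5, 6), c(1, 2, 3, 4, 5, 6))
  rec <- correlate_cpg_gene(f$beta, f$expr, f$cand, f$samples)
  expect_true(rec$degenerate)
  expect_true(is.na(rec$p_value))
  expect_false(rec$passes)
})

test_that("rho agrees with the brute-force covariance formula on random pairs", {
  set.seed(405)
  for (i in 1:100) {
    f <- cor_fixture(runif(6), rnorm(6, 5, 2))
    rec <- correlate_cpg_gene(f$beta, f$expr, f$cand, f$samples)
    expect_equal(rec$rho, oracle_pearson(f$beta[1, ], f$expr[1, ]),
                 tolerance = 1e-12)
  }
})

test_that("input validation names the offending sample", {
  f <- cor_fixture(runif(6), rnorm(6))
  expect_error(correlate_cpg_gene(f$beta, f$expr, f$cand, f$samples[1:2]),
               "at least 3")
  expect_error(
    correlate_cpg_gene(f$beta, f$expr[, 1:5, drop = FALSE], f$cand, f$samples),
    "s6.*no expression")
})

make_records <- function(genes, rhos, p_corr = 0.01) {
  data.frame(
    probe_id = sprintf("cg%03d", seq_along(genes)),
    gene = genes, region = "TSS200", rho = rhos,
    p_value = p_corr / 2, p_corr = p_corr, n_samples = 6L,
    degenerate = FALSE, passes = abs(rhos) >= 0.7 & p_corr <= 0.05,
    stringsAsFactors = FALSE
  )
}

de_for <- function(genes, log2fc, p_fdr = 1e-6) {
  data.frame(gene = genes, mean_expression = 5, log2fc = log2fc,
             p_value = p_fdr / 2, p_fdr = p_fdr,
             significant = p_fdr < 0.05, stringsAsFactors = FALSE)
}

test_that("signature selection applies the >=3 CpG and sign rules", {
  # RAB32-like: 3 CpGs all strongly negative -> included with sign '-'
  rec <- make_records(rep("RAB32L", 3), c(-0.97, -0.9, -0.84))
  sig <- select_signature_genes(rec, de_for("RAB32L", -4.42))
  expect_equal(sig$gene, "RAB32L")
  expect_equal(sig$correlation_sign, "-")
  expect_equal(sig$n_cpgs, 3L)

  # only 2 passing CpGs -> excluded
  rec2 <- make_records(rep("TWOCPG", 2), c(-0.95, -0.9))
  expect_equal(nrow(select_signature_genes(rec2, de_for("TWOCPG", -3))), 0L)

  # MACROD2-like: 9 positive CpGs -> included with sign '+'
  rec3 <- make_records(rep("MACRODL", 9), seq(0.86, 0.99, length.out = 9))
  sig3 <- select_signature_genes(rec3, de_for("MACRODL", 5.83))
  expect_equal(sig3$correlation_sign, "+")
  expect_equal(sig3$n_cpgs, 9L)
})

test_that("a gene with discordant passing CpGs is labelled mixed", {
  rec <- make_records(rep("PLEKHG5L", 4), c(-0.9, -0.85, -0.8, 0.88))
  sig <- select_signature_genes(rec, de_for("PLEKHG5L", -2))
  expect_equal(sig$correlation_sign, "mixed")
})

test_that("non-significant DE genes and sub-threshold rho are excluded", {
  rec <- make_records(rep("G1", 3), c(-0.95, -0.9, -0.85))
  expect_equal(nrow(select_signature_genes(rec, de_for("G1", -3, p_fdr = 0.2))), 0L)
  weak <- make_records(rep("G2", 3), c(-0.6, -0.5, -0.65))
  expect_equal(nrow(select_signature_genes(weak, de_for("G2", -3))), 0L)
})

test_that("every reported signature gene satisfies its invariants (self-audit)", {
  set.seed(406)
  run <- run_pipeline(simulate_dataset(small_config(seed = 42)))
  sig <- run$signature
  for (i in seq_len(nrow(sig))) {
    cpgs <- strsplit(sig$cpgs[i], ";")[[1]]
    expect_gte(length(cpgs), 3L)
    rec <- run$records[run$records$gene == sig$gene[i] &
                         run$records$probe_id %in% cpgs, ]
    expect_true(all(abs(rec$rho) >= 0.7))
    expect_true(all(rec$p_corr <= 0.05))
    expect_true(sig$gene[i] %in% run$de$gene[run$de$significant])
  }
})
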