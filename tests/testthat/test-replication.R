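pair_beta <- function(diffs_by_probe, base = 0.4) {
  # build a beta matrix realizing the given per-probe paired differences
  n_pairs <- ncol(diffs_by_probe)
  diag_ids <- sprintf("A%d_d", seq_len(n_pairs))
  rem_ids <- sprintf("A%d_r", seq_len(n_pairs))
  rem <- matrix(base, nrow(diffs_by_probe), n_pairs)
  m <- cbind(rem + diffs_by_probe, rem)
  rownames(m) <- rownames(diffs_by_probe)
  colnames(m) <- c(diag_ids, rem_ids)
  list(beta = m, pairs = data.frame(diagnosis = diag_ids, remission = rem_ids))
}

test_that("paired t statistic matches the closed form on the worked diffs", {
  d <- matrix(c(0.35, 0.40, 0.45), 1, dimnames = list("cg1", NULL))
  x <- pair_beta(d)
  res <- paired_t_test(x$beta, x$pairs)
  expect_equal(res$mean_paired_diff, 0.40, tolerance = 1e-12)
  expect_equal(res$sd_paired_diff, 0.05, tolerance = 1e-12)
  expect_equal(round(res$t_stat, 4), 13.8564)
  expect_equal(res$n_pairs, 3L)
  expect_equal(res$direction, "hyper")
})

test_that("symmetric differences give t = 0 and p = 1", {
  d <- matrix(c(0.10, -0.10, 0.00), 1, dimnames = list("cg1", NULL))
  x <- pair_beta(d)
  res <- paired_t_test(x$beta, x$pairs)
  expect_equal(res$mean_paired_diff, 0, tolerance = 1e-12)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
})

test_that("zero spread with nonzero effect is degenerate and maximally significant", {
  d <- matrix(c(0.40, 0.40, 0.40), 1, dimnames = list("cg1", NULL))
  x <- pair_beta(d)
  res <- paired_t_test(x$beta, x$pairs)
  expect_true(res$degenerate)
  expect_equal(res$sd_paired_diff, 0)
  expect_equal(res$p_value, 0)
  expect_equal(res$direction, "hyper")
})

test_that("t and p agree with stats::t.test on random inputs", {
  set.seed(402)
  beta <- random_beta(60, c("A1_d", "A1_r", "A2_d", "A2_r", "A3_d", "A3_r"))
  pairs <- data.frame(diagnosis = c("A1_d", "A2_d", "A3_d"),
                      remission = c("A1_r", "A2_r", "A3_r"))
  res <- paired_t_test(beta, pairs)
  for (i in seq_len(nrow(res))) {
    p <- res$probe_id[i]
    tt <- t.test(beta[p, pairs$diagnosis], beta[p, pairs$remission],
                 paired = TRUE)
    expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-9)
  }
})

test_that("pairs are validated", {
  beta <- random_beta(5, c("a", "b", "c", "d"))
  expect_error(paired_t_test(beta, data.frame(diagnosis = "a", remission = "b")),
               "at least 2")
  expect_error(paired_t_test(beta, data.frame(diagnosis = c("a", "a"),
                                              remission = c("b", "c"))),
               "more than one pair")
})

test_that("replication intersects on effect size and direction", {
  twin <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    delta_proband_twin = c(0.5, 0.5, 0.5, 0.5),
    delta_proband_remission = c(0.5, 0.5, 0.5, 0.5),
    delta_healthy = 0,
    direction = "hyper",
    retained = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  rep <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    mean_paired_diff = c(0.45, -0.45, 0.25, 0.45),
    sd_paired_diff = 0.01, t_stat = 10, p_value = 0.001, n_pairs = 3L,
    direction = c("hyper", "hypo", "hyper", "hyper"),
    degenerate = FALSE, stringsAsFactors = FALSE
  )
  out <- replicate_intersect(twin, rep)
  expect_equal(out$probe_id, "p1")                 # p2 flips, p3 too weak,
  expect_equal(attr(out, "direction_counts")[["hyper"]], 1L)  # p4 not retained
})

test_that("the effect bound is strict and the replicated set is a subset", {
  twin <- data.frame(probe_id = "p1", delta_proband_twin = 0.5,
                     delta_proband_remission = 0.5, delta_healthy = 0,
                     direction = "hyper", retained = TRUE,
                     stringsAsFactors = FALSE)
  rep <- data.frame(probe_id = "p1", mean_paired_diff = 0.30,
                    sd_paired_diff = 0.01, t_stat = 10, p_value = 1e-4,
                    n_pairs = 3L, direction = "hyper", degenerate = FALSE,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(replicate_intersect(twin, rep)), 0L)  # 0.30 not > 0.30
  expect_equal(nrow(replicate_intersect(twin, rep, strict = FALSE)), 1L)

  set.seed(403)
  beta <- random_beta(300, c("S1", "S2", "S3",
                             "A1_d", "A1_r", "A2_d", "A2_r", "A3_d", "A3_r"))
  twin_all <- twin_delta_filter(beta, "S1", "S2", "S3")
  rep_all <- paired_t_test(beta, data.frame(
    diagnosis = c("A1_d", "A2_d", "A3_d"),
    remission = c("A1_r", "A2_r", "A3_r")))
  out <- replicate_intersect(twin_all, rep_all)
  expect_true(all(out$probe_id %in% twin_all$probe_id[twin_all$retained]))
})

test_that("an optional p-value cutoff can be applied", {
  twin <- data.frame(probe_id = c("p1", "p2"),
                     delta_proband_twin = 0.5, delta_proband_remission = 0.5,
                     delta_healthy = 0, direction = "hyper", retained = TRUE,
                     stringsAsFactors = FALSE)
  rep <- data.frame(probe_id = c("p1", "p2"),
                    mean_paired_diff = c(0.45, 0.45), sd_paired_diff = 0.01,
                    t_stat = 10, p_value = c(0.001, 0.20), n_pairs = 3L,
                    direction = "hyper", degenerate = FALSE,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(replicate_intersect(twin, rep)), 2L)
  expect_equal(replicate_intersect(twin, rep, rep_alpha = 0.05)$probe_id, "p1")
})
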