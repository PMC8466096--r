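#' Per-probe paired t-test across diagnosis-remission pairs
#'
#' For every probe, computes paired differences d_i = beta(diagnosis_i) -
#' beta(remission_i) over the pairs with both values present, the mean paired
#' difference (the effect size of this analysis), its sd, the paired t
#' statistic t = mean / (sd / sqrt(n)) with df = n - 1, and a two-sided p from
#' the Student t distribution. Probes with fewer than two complete pairs are
#' excluded. When all differences are identical the sd is zero and the test is
#' degenerate: such probes are flagged, with p reported as 0 when the common
#' difference is nonzero (maximally consistent effect) and 1 when it is zero.
#'
#' @param beta numeric probes x samples beta matrix.
#' @param pairs diagnosis-remission sample pairs: a two-column data.frame
#'   (diagnosis, remission) or a list of length-2 vectors; at least 2 pairs,
#'   no sample reused.
#' @return data.frame with `probe_id`, `mean_paired_diff`, `sd_paired_diff`,
#'   `t_stat`, `p_value`, `n_pairs`, `direction` (hyper when the mean
#'   difference is positive, hypo when negative) and `degenerate`.
#' @export
paired_t_test <- function(beta, pairs) {
  check_beta_matrix(beta)
  pairs <- as_pair_frame(pairs)
  if (nrow(pairs) < 2L)
    stop_input("at least 2 diagnosis-remission pairs are required")
  check_samples_present(c(pairs$diagnosis, pairs$remission), colnames(beta))

  d <- beta[, pairs$diagnosis, drop = FALSE] -
       beta[, pairs$remission, drop = FALSE]
  n <- rowSums(!is.na(d))
  keep <- n >= 2L
  d <- d[keep, , drop = FALSE]
  n <- n[keep]

  mean_d <- rowMeans(d, na.rm = TRUE)
  sd_d <- sqrt(rowSums((d - mean_d)^2, na.rm = TRUE) / (n - 1))
  degenerate <- sd_d == 0
  t_stat <- ifelse(degenerate, ifelse(mean_d == 0, 0, Inf * sign(mean_d)),
                   mean_d / (sd_d / sqrt(n)))
  p <- ifelse(degenerate, ifelse(mean_d == 0, 1, 0),
              2 * stats::pt(-abs(t_stat), df = n - 1))

  out <- data.frame(
    probe_id = rownames(d),
    mean_paired_diff = unname(mean_d),
    sd_paired_diff = unname(sd_d),
    t_stat = unname(t_stat),
    p_value = unname(p),
    n_pairs = unname(n),
    direction = ifelse(mean_d > 0, "hyper", ifelse(mean_d < 0, "hypo", "none")),
    degenerate = unname(degenerate),
    stringsAsFactors = FALSE
  )
  attr(out, "n_excluded_incomplete") <- sum(!keep)
  out
}

#' Intersect twin-filtered probes with the replication cohort
#'
#' A twin-filtered probe replicates when its mean paired diagnosis-remission
#' difference exceeds `effect_min` in magnitude (strictly, |effect| > 30% by
#' default; set `strict = FALSE` for an inclusive bound) with the same
#' direction as in the twin contrast. Twin-filter probes labelled
#' `discordant` carry no direction and cannot replicate. No p-value cutoff is
#' applied unless `rep_alpha` is given, since the replication criterion is
#' effect size and direction.
#'
#' @param twin_results output of [twin_delta_filter()].
#' @param rep_results output of [paired_t_test()].
#' @param effect_min minimum |mean paired difference|.
#' @param strict use strict inequality (> effect_min) as stated for the
#'   replication effect criterion; the twin filter uses >= for its own bound.
#' @param rep_alpha optional p-value cutoff (off by default).
#' @return data.frame of replicated probes (`probe_id`, `direction`,
#'   `mean_paired_diff`, `p_value`), a subset of the twin-retained set;
#'   attribute `direction_counts` gives the per-direction tally.
#' @export
replicate_intersect <- function(twin_results, rep_results, effect_min = 0.30,
                                strict = TRUE, rep_alpha = NULL) {
  if (nrow(twin_results) == 0L || nrow(rep_results) == 0L)
    stop_input("both twin and replication results must be nonempty")
  twin <- twin_results[twin_results$retained &
                         twin_results$direction %in% c("hyper", "hypo"), ]
  m <- merge(twin[, c("probe_id", "direction")],
             rep_results[, c("probe_id", "mean_paired_diff", "direction",
                             "p_value")],
             by = "probe_id", suffixes = c("_twin", "_rep"))
  big <- if (strict) abs(m$mean_paired_diff) > effect_min
         else abs(m$mean_paired_diff) >= effect_min
  ok <- big & m$direction_twin == m$direction_rep
  if (!is.null(rep_alpha)) ok <- ok & m$p_value <= rep_alpha
  out <- data.frame(
    probe_id = m$probe_id[ok],
    direction = m$direction_twin[ok],
    mean_paired_diff = m$mean_paired_diff[ok],
    p_value = m$p_value[ok],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "direction_counts") <- c(
    hyper = sum(out$direction == "hyper"),
    hypo = sum(out$direction == "hypo")
  )
  out
}
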