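#' Twin-contrast delta-beta filter
#'
#' Identifies leukemia-related methylation changes in the proband by the
#' discordant-twin contrast: a probe is retained when the proband differs from
#' both her healthy twin and her own remission sample by at least `delta_min`
#' in beta (|delta| >= 0.30 by default) while the two healthy samples agree to
#' within `delta_max_healthy` (|delta| <= 0.10 by default). All deltas are
#' signed proband-minus-healthy; a retained probe is labelled `hyper` when
#' both proband contrasts are positive, `hypo` when both are negative, and
#' `discordant` when the magnitudes pass with opposite signs (such probes are
#' excluded from direction counts). Probes with a missing value in any of the
#' three samples are excluded and counted.
#'
#' @param beta numeric probes x samples matrix of beta values in [0,1] with
#'   probe rownames and sample colnames.
#' @param proband,twin,remission the three sample ids of the trio.
#' @param delta_min inclusive minimum |delta beta| for both proband contrasts.
#' @param delta_max_healthy inclusive maximum |delta beta| between the two
#'   healthy samples.
#' @return data.frame with one row per complete probe: `probe_id`,
#'   `delta_proband_twin`, `delta_proband_remission`, `delta_healthy`,
#'   `direction` and `retained`; attribute `n_excluded_missing` counts probes
#'   dropped for missingness.
#' @export
twin_delta_filter <- function(beta, proband, twin, remission,
                              delta_min = 0.30, delta_max_healthy = 0.10) {
  check_beta_matrix(beta)
  ids <- c(proband = proband, twin = twin, remission = remission)
  check_samples_present(ids, colnames(beta))
  if (anyDuplicated(ids))
    stop_input("proband, twin and remission must be three distinct samples")

  b <- beta[, ids, drop = FALSE]
  complete <- stats::complete.cases(b)
  n_excluded <- sum(!complete)
  b <- b[complete, , drop = FALSE]

  d_twin <- b[, 1] - b[, 2]
  d_rem <- b[, 1] - b[, 3]
  d_healthy <- b[, 2] - b[, 3]
  retained <- abs(d_twin) >= delta_min & abs(d_rem) >= delta_min &
    abs(d_healthy) <= delta_max_healthy
  direction <- ifelse(d_twin > 0 & d_rem > 0, "hyper",
               ifelse(d_twin < 0 & d_rem < 0, "hypo", "discordant"))

  out <- data.frame(
    probe_id = rownames(b),
    delta_proband_twin = unname(d_twin),
    delta_proband_remission = unname(d_rem),
    delta_healthy = unname(d_healthy),
    direction = direction,
    retained = unname(retained),
    stringsAsFactors = FALSE
  )
  attr(out, "n_excluded_missing") <- n_excluded
  attr(out, "thresholds") <- c(delta_min = delta_min,
                               delta_max_healthy = delta_max_healthy)
  out
}
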