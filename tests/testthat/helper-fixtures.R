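# fixtures and independent brute-force oracles used across the suite

# small beta matrix with named probes/samples
make_beta <- function(values, probes = NULL, samples = NULL) {
  m <- matrix(values, nrow = if (is.null(probes)) 1 else length(probes),
              byrow = TRUE)
  rownames(m) <- if (is.null(probes)) paste0("cg", seq_len(nrow(m))) else probes
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  m
}

random_beta <- function(n_probes, samples, na_rate = 0) {
  m <- matrix(runif(n_probes * length(samples)), n_probes,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)), samples))
  if (na_rate > 0) m[runif(length(m)) < na_rate] <- NA
  m
}

# scaled-down generator configuration for fast unit tests
small_config <- function(...) {
  args <- list(n_probes = 2000, n_genes = 300, n_signature_genes = 8,
               cpgs_per_signature_gene = 3, n_composition_probes = 20,
               n_de_genes = 30)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# --- brute-force oracles -----------------------------------------------------

oracle_twin_filter <- function(beta, proband, twin, remission,
                               delta_min = 0.30, delta_max_healthy = 0.10) {
  out <- NULL
  for (p in rownames(beta)) {
    b1 <- beta[p, proband]; b2 <- beta[p, twin]; b3 <- beta[p, remission]
    if (is.na(b1) || is.na(b2) || is.na(b3)) next
    retained <- abs(b1 - b2) >= delta_min && abs(b1 - b3) >= delta_min &&
      abs(b2 - b3) <= delta_max_healthy
    dir <- if (b1 - b2 > 0 && b1 - b3 > 0) "hyper"
           else if (b1 - b2 < 0 && b1 - b3 < 0) "hypo" else "discordant"
    out <- rbind(out, data.frame(probe_id = p, retained = retained,
                                 direction = dir, stringsAsFactors = FALSE))
  }
  out
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- min(running, 1)
  }
  adj[order(o)]
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_distance <- function(beta, a, b) {
  x <- beta[, a]; y <- beta[, b]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  sqrt(sum((x[ok] - y[ok])^2) * nrow(beta) / sum(ok))
}

# mean 1-D silhouette of scores grouped by labels
silhouette_1d <- function(scores, labels) {
  n <- length(scores)
  mean(vapply(seq_len(n), function(i) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) return(NA_real_)
    a <- mean(abs(scores[i] - scores[same]))
    b <- mean(abs(scores[i] - scores[labels != labels[i]]))
    (b - a) / max(a, b)
  }, numeric(1)), na.rm = TRUE)
}
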