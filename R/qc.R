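#' Pairwise Euclidean distances between methylation profiles
#'
#' Euclidean distance over the probes non-missing in both samples of each
#' pair, rescaled by sqrt(P / P_shared) to correct for differing missingness
#' (the scaling [stats::dist()] applies to missing data).
#'
#' @param beta probes x samples beta matrix.
#' @param samples optional subset of sample ids (default: all).
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
beta_distance_matrix <- function(beta, samples = NULL) {
  check_beta_matrix(beta)
  if (is.null(samples)) samples <- colnames(beta)
  check_samples_present(samples, colnames(beta))
  if (length(samples) < 2L)
    stop_input("at least 2 samples are required")
  d <- as.matrix(stats::dist(t(beta[, samples, drop = FALSE]),
                             method = "euclidean"))
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    stop_input("no shared probes between samples '%s' and '%s'",
               samples[bad[1]], samples[bad[2]])
  }
  d
}

#' Agglomerative clustering and first-split purity
#'
#' Clusters the distance matrix (complete linkage by default), cuts the
#' dendrogram into two clusters, and scores how cleanly that first separation
#' divides leukemic from non-leukemic samples: the purity is the fraction of
#' samples whose cluster's majority label matches their own. When all
#' distances are (numerically) zero the split is arbitrary and the result is
#' flagged degenerate.
#'
#' @param distances symmetric distance matrix or `dist` object.
#' @param labels per-sample labels (e.g. leukemic / non-leukemic), named by
#'   sample or aligned with the distance matrix.
#' @param linkage hclust linkage method (complete, average, ward.D2, ...).
#' @return list with `hclust`, `assignment` (two-cluster cut), `purity` and
#'   `degenerate`.
#' @export
cluster_and_purity <- function(distances, labels, linkage = "complete") {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  if (n < 2L) stop_input("at least 2 samples are required for clustering")
  ids <- attr(d, "Labels")
  if (!is.null(names(labels))) {
    check_samples_present(ids, names(labels))
    labels <- labels[ids]
  } else if (length(labels) != n) {
    stop_input("'labels' must be named or have one entry per sample")
  }
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = 2)
  purity <- mean(unlist(lapply(split(labels, cl), function(lab) {
    lab == names(which.max(table(lab)))
  })))
  list(hclust = hc, assignment = cl, purity = purity,
       degenerate = max(d) < 1e-12)
}

#' Targeted principal component analysis on selected CpG sites
#'
#' Column-centered (per probe), unscaled PCA of the samples over the given
#' probe set, the "targeted" view used to check that the selected CpG panel
#' separates leukemic from non-leukemic samples independent of blood cell
#' composition (reference CD34+/CD19+ profiles included among the samples).
#' Probes missing in any selected sample are dropped and counted. Component
#' signs follow a fixed convention (the largest-magnitude loading of each
#' component is positive) so the output is fully deterministic. Optionally the
#' beta values are logit-transformed to M-values first.
#'
#' @param beta probes x samples beta matrix.
#' @param probes probe ids to analyze (must exist in the matrix).
#' @param samples optional subset of sample ids (default: all).
#' @param m_values transform to M = log2(beta / (1 - beta)) with beta clipped
#'   to [0.001, 0.999] before the PCA.
#' @return object of class `twinmeth_pca`: list with `scores` (samples x
#'   components), `explained_variance_fraction`, `loadings`,
#'   `loadings_available`, `n_probes_dropped`, `degenerate`.
#' @export
pca_top_sites <- function(beta, probes, samples = NULL, m_values = FALSE) {
  check_beta_matrix(beta)
  if (is.null(samples)) samples <- colnames(beta)
  check_samples_present(samples, colnames(beta))
  check_samples_present(probes, rownames(beta), "probe")
  if (length(samples) < 2L || length(probes) < 2L)
    stop_input("PCA needs at least 2 samples and 2 probes")

  x <- beta[probes, samples, drop = FALSE]
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 2L)
    stop_input("fewer than 2 complete probes after dropping missingness")
  if (m_values) {
    x <- pmin(pmax(x, 0.001), 0.999)
    x <- log2(x / (1 - x))
  }
  x <- t(x)  # samples x probes
  centered <- scale(x, center = TRUE, scale = FALSE)
  if (max(abs(centered)) < 1e-12) {
    k <- min(nrow(x) - 1L, ncol(x))
    scores <- matrix(0, nrow(x), k,
                     dimnames = list(rownames(x), paste0("PC", seq_len(k))))
    return(structure(list(scores = scores,
                          explained_variance_fraction = rep(NA_real_, k),
                          loadings = NULL, loadings_available = FALSE,
                          n_probes_dropped = n_dropped, degenerate = TRUE),
                     class = "twinmeth_pca"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # sign convention: largest-magnitude loading positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(
    scores = pc$x,
    explained_variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
    loadings = pc$rotation,
    loadings_available = TRUE,
    n_probes_dropped = n_dropped,
    degenerate = FALSE
  ), class = "twinmeth_pca")
}

#' @export
print.twinmeth_pca <- function(x, ...) {
  if (x$degenerate) {
    cat("Targeted PCA: degenerate (no variance between samples)\n")
  } else {
    ev <- round(100 * x$explained_variance_fraction[1:min(3, length(x$explained_variance_fraction))], 1)
    cat(sprintf("Targeted PCA on %d samples: %s%% variance on first components (%d probes dropped for missingness)\n",
                nrow(x$scores), paste(ev, collapse = "/"), x$n_probes_dropped))
  }
  invisible(x)
}

#' Parental comparability of signature CpGs
#'
#' Checks that the parents' methylation at the signature CpGs is comparable to
#' a healthy reference group, excluding an inherited deregulated pattern: a
#' probe is comparable when every parent is within `tolerance` of the
#' reference mean.
#'
#' @param signature_probes probe ids to check.
#' @param beta probes x samples beta matrix.
#' @param parents parent sample ids.
#' @param healthy_refs healthy reference sample ids (nonempty).
#' @param tolerance maximum |beta_parent - mean(beta_refs)| per probe.
#' @return data.frame (`probe_id`, `comparable`) with attribute
#'   `fraction_comparable`.
#' @export
parental_check <- function(signature_probes, beta, parents, healthy_refs,
                           tolerance = 0.10) {
  check_beta_matrix(beta)
  if (length(healthy_refs) == 0L)
    stop_input("'healthy_refs' must be nonempty")
  check_samples_present(c(parents, healthy_refs), colnames(beta))
  check_samples_present(signature_probes, rownames(beta), "probe")

  ref_mean <- rowMeans(beta[signature_probes, healthy_refs, drop = FALSE],
                       na.rm = TRUE)
  dev <- abs(beta[signature_probes, parents, drop = FALSE] - ref_mean)
  comparable <- apply(dev <= tolerance, 1, all)
  out <- data.frame(probe_id = signature_probes,
                    comparable = unname(comparable),
                    stringsAsFactors = FALSE)
  attr(out, "fraction_comparable") <- mean(comparable, na.rm = TRUE)
  out
}
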