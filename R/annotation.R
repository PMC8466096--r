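#' Expand a 450K-dialect manifest into one row per (probe, gene, region)
#'
#' Splits the semicolon-joined `UCSC_RefGene_Name` / `UCSC_RefGene_Group`
#' columns and drops duplicate (gene, region) entries per probe.
#'
#' @param manifest a manifest data.frame with columns `IlmnID`,
#'   `UCSC_RefGene_Name`, `UCSC_RefGene_Group` (a `cpg_manifest` object is
#'   also accepted).
#' @return data.frame with columns `probe_id`, `gene`, `region`.
#' @export
manifest_annotations <- function(manifest) {
  if (inherits(manifest, "cpg_manifest")) manifest <- manifest$manifest
  need <- c("IlmnID", "UCSC_RefGene_Name", "UCSC_RefGene_Group")
  if (!all(need %in% names(manifest)))
    stop_input("manifest must have columns %s", paste(need, collapse = ", "))
  genes <- strsplit(manifest$UCSC_RefGene_Name, ";", fixed = TRUE)
  regions <- strsplit(manifest$UCSC_RefGene_Group, ";", fixed = TRUE)
  ng <- lengths(genes)
  nr <- lengths(regions)
  if (any(ng != nr))
    stop_input("gene and region annotation lists disagree in length for %d probes",
               sum(ng != nr))
  out <- data.frame(
    probe_id = rep(manifest$IlmnID, ng),
    gene = unlist(genes),
    region = unlist(regions),
    stringsAsFactors = FALSE
  )
  out <- out[out$gene != "", , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Map probes to their gene and region annotations
#'
#' Pure manifest lookup: every input probe is accounted for; probes absent
#' from the manifest or carrying no gene annotation map to nothing and are
#' counted as unannotated. Multi-gene probes map to all their genes.
#'
#' @param probes character vector of probe ids.
#' @param manifest manifest data.frame or `cpg_manifest` object.
#' @return data.frame (`probe_id`, `gene`, `region`) restricted to the input
#'   probes, with attributes `probes` (the query), `unannotated` (probes with
#'   no annotation), `n_distinct_genes` and `n_distinct_gene_regions`.
#' @export
annotate_probes <- function(probes, manifest) {
  probes <- unique(as.character(probes))
  ann <- manifest_annotations(manifest)
  out <- ann[ann$probe_id %in% probes, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "probes") <- probes
  attr(out, "unannotated") <- setdiff(probes, out$probe_id)
  attr(out, "n_distinct_genes") <- length(unique(out$gene))
  attr(out, "n_distinct_gene_regions") <-
    nrow(unique(out[, c("gene", "region")]))
  out
}

#' Fraction of probes annotated to a region set
#'
#' Reports the fraction of probes having at least one annotation in `regions`
#' (default: the promoter, TSS1500 or TSS200 - within 1500 bp or 200 bp
#' upstream of a transcription start site).
#'
#' @param probes nonempty character vector of probe ids.
#' @param manifest manifest data.frame or `cpg_manifest` object.
#' @param regions region categories counted as a hit.
#' @return fraction in [0,1] with attributes `numerator` and `denominator`.
#' @export
region_fraction <- function(probes, manifest,
                            regions = c("TSS1500", "TSS200")) {
  probes <- unique(as.character(probes))
  if (length(probes) == 0L)
    stop_input("'probes' must be nonempty")
  ann <- annotate_probes(probes, manifest)
  hit <- unique(ann$probe_id[ann$region %in% regions])
  out <- length(hit) / length(probes)
  attr(out, "numerator") <- length(hit)
  attr(out, "denominator") <- length(probes)
  out
}
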