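#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `beta.tsv` and `counts.tsv` (tab-separated, first column the probe or
#' gene id, header row of sample ids), `manifest.csv` and `samples.csv`
#' (comma-separated), and `truth.json` (probe- and gene-level ground truth plus
#' the generating configuration). Writing the same dataset twice produces
#' identical files, and [read_dataset()] reproduces the in-memory dataset.
#'
#' @param dataset a `twinmeth_sim` object from [simulate_dataset()].
#' @param directory output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, directory) {
  if (!inherits(dataset, "twinmeth_sim"))
    stop_input("'dataset' must be a twinmeth_sim object")
  if (is.null(dataset$beta) || nrow(dataset$beta) == 0L)
    stop_input("refusing to write an empty dataset")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop_input("cannot create directory '%s'", directory)

  write_matrix <- function(m, path, id_col) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_col
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- file.path(directory,
                     c("beta.tsv", "counts.tsv", "manifest.csv",
                       "samples.csv", "truth.json"))
  write_matrix(dataset$beta, paths[1], "probe_id")
  write_matrix(dataset$counts, paths[2], "gene_id")
  utils::write.csv(dataset$manifest, paths[3], row.names = FALSE, quote = TRUE)
  utils::write.csv(dataset$samples, paths[4], row.names = FALSE, quote = TRUE)
  jsonlite::write_json(
    list(config = unclass(dataset$config),
         probes = dataset$truth$probes,
         genes = dataset$truth$genes),
    paths[5], auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory the directory containing the five dataset files.
#' @return a `twinmeth_sim` object equal to the one written.
#' @export
read_dataset <- function(directory) {
  need <- file.path(directory, c("beta.tsv", "counts.tsv", "manifest.csv",
                                 "samples.csv", "truth.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop_input("dataset files missing: %s", paste(missing, collapse = ", "))

  read_matrix <- function(path, mode) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- mode
    m
  }
  beta <- read_matrix(need[1], "double")
  counts <- read_matrix(need[2], "integer")
  manifest <- utils::read.csv(need[3], stringsAsFactors = FALSE,
                              colClasses = c(CHR = "character"))
  manifest$UCSC_RefGene_Name[is.na(manifest$UCSC_RefGene_Name)] <- ""
  manifest$UCSC_RefGene_Group[is.na(manifest$UCSC_RefGene_Group)] <- ""
  samples <- utils::read.csv(need[4], stringsAsFactors = FALSE,
                             colClasses = c(pair_id = "character"))
  samples$pair_id[is.na(samples$pair_id)] <- ""
  tr <- jsonlite::read_json(need[5], simplifyVector = TRUE)
  config <- do.call(sim_config, tr$config[setdiff(names(tr$config), character(0))])
  probes <- as.data.frame(tr$probes, stringsAsFactors = FALSE)
  genes <- as.data.frame(tr$genes, stringsAsFactors = FALSE)

  structure(
    list(config = config, manifest = manifest, beta = beta,
         samples = samples, counts = counts,
         truth = list(probes = probes, genes = genes)),
    class = "twinmeth_sim"
  )
}
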