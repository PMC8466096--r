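# Internal input validators shared across stages.

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_beta_matrix <- function(beta, arg = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop_input("'%s' must be a numeric matrix (probes x samples)", arg)
  if (nrow(beta) == 0L || ncol(beta) == 0L)
    stop_input("'%s' is empty", arg)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop_input("'%s' needs probe rownames and sample colnames", arg)
  if (anyDuplicated(rownames(beta)))
    stop_input("duplicated probe ids in '%s'", arg)
  if (anyDuplicated(colnames(beta)))
    stop_input("duplicated sample ids in '%s'", arg)
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop_input("'%s' contains values outside [0, 1]", arg)
  invisible(beta)
}

check_samples_present <- function(ids, have, what = "sample") {
  missing <- setdiff(ids, have)
  if (length(missing))
    stop_input("unknown %s id(s): %s", what, paste(missing, collapse = ", "))
  invisible(ids)
}

# pairs given as a 2-column data.frame/matrix (diagnosis, remission) or a
# list of length-2 vectors; normalised to a data.frame.
as_pair_frame <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    if (!all(lengths(pairs) == 2L))
      stop_input("each pair must have exactly a diagnosis and a remission id")
    pairs <- data.frame(
      diagnosis = vapply(pairs, `[[`, "", 1L),
      remission = vapply(pairs, `[[`, "", 2L),
      stringsAsFactors = FALSE
    )
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L)
    stop_input("'pairs' must have two columns: diagnosis, remission")
  names(pairs)[1:2] <- c("diagnosis", "remission")
  pairs$diagnosis <- as.character(pairs$diagnosis)
  pairs$remission <- as.character(pairs$remission)
  all_ids <- c(pairs$diagnosis, pairs$remission)
  if (anyDuplicated(all_ids))
    stop_input("a sample id appears in more than one pair")
  pairs
}
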