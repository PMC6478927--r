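#' Read batch container
#'
#' A thin data-frame wrapper used by the preprocessing stages: columns
#' `read_id`, `seq`, and (after [collapse_duplicates()]) `multiplicity`.
#'
#' @param read_id,seq character vectors of equal length.
#' @return A `read_batch` data frame.
#' @export
read_batch <- function(read_id, seq) {
  if (any(!nzchar(seq))) stop("empty read sequence")
  structure(data.frame(read_id = as.character(read_id),
                       seq = as.character(seq), stringsAsFactors = FALSE),
            class = c("read_batch", "data.frame"))
}

#' Read a FASTQ file into a read batch
#' @param path FASTQ file.
#' @return A [read_batch()].
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", ln[seq(1, length(ln), by = 4L)]))
  read_batch(ids, ln[seq(2, length(ln), by = 4L)])
}

#' Write a read batch as FASTQ
#' @param batch a [read_batch()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(batch, path) {
  writeLines(as.vector(rbind(paste0("@", batch$read_id), batch$seq, "+",
                             strrep("I", nchar(batch$seq)))), path)
  invisible(path)
}

#' Demultiplex reads by experimental barcode
#'
#' Assigns each read to the sample whose barcode is an exact prefix of the
#' read sequence and strips the barcode; reads matching no barcode go to
#' the `"unassigned"` bin with their sequence untouched.
#'
#' @param batch a [read_batch()].
#' @param barcode_map named character vector, sample name -> barcode
#'   (equal-length, prefix-encoded, no duplicates).
#' @return Named list of [read_batch()] objects (one per sample, plus
#'   `unassigned`), with a `counts` attribute.
#' @export
demultiplex <- function(batch, barcode_map) {
  if (anyDuplicated(barcode_map)) stop("duplicate barcode in map")
  if (length(unique(nchar(barcode_map))) != 1L)
    stop("barcodes must be equal length")
  bw <- nchar(barcode_map[1])
  prefix <- substr(batch$seq, 1L, bw)
  sample <- names(barcode_map)[match(prefix, barcode_map)]
  out <- lapply(stats::setNames(nm = names(barcode_map)), function(s) {
    w <- which(!is.na(sample) & sample == s)
    read_batch(batch$read_id[w], substring(batch$seq[w], bw + 1L))
  })
  w <- which(is.na(sample))
  out$unassigned <- read_batch(batch$read_id[w], batch$seq[w])
  attr(out, "counts") <- vapply(out, nrow, integer(1))
  out
}

#' Sequence-based PCR duplicate collapse
#'
#' Reads with identical sequence collapse to their first occurrence; the
#' survivor records how many copies it absorbed (`multiplicity`).
#'
#' @param batch a [read_batch()].
#' @return A [read_batch()] with a `multiplicity` column.
#' @export
collapse_duplicates <- function(batch) {
  if (nrow(batch) == 0) {
    batch$multiplicity <- integer(0)
    return(batch)
  }
  first <- !duplicated(batch$seq)
  out <- batch[first, , drop = FALSE]
  out$multiplicity <- as.integer(table(factor(batch$seq,
                                              levels = out$seq)))
  rownames(out) <- NULL
  out
}

#' Discard reads shorter than a minimum length
#'
#' The boundary is strict: a `min_len`-nt read is retained, anything
#' shorter is discarded.
#'
#' @param batch a [read_batch()].
#' @param min_len minimum retained length (default 20 nt).
#' @return The filtered [read_batch()] with a `n_discarded` attribute.
#' @export
filter_short <- function(batch, min_len = 20L) {
  stopifnot(min_len >= 1L)
  keep <- nchar(batch$seq) >= min_len
  out <- batch[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Full preprocessing of a multiplexed FASTQ batch
#'
#' Demultiplex, collapse PCR duplicates, and apply the 20-nt length
#' filter, returning per-sample surviving batches plus a count summary.
#'
#' @param batch a [read_batch()] (barcoded, multiplexed).
#' @param barcode_map named character vector, sample -> barcode.
#' @param min_len minimum retained read length.
#' @return List with `samples` (named list of batches) and `summary`
#'   (data frame of per-stage counts).
#' @export
preprocess_reads <- function(batch, barcode_map, min_len = 20L) {
  dm <- demultiplex(batch, barcode_map)
  samples <- list()
  rows <- list()
  for (s in names(barcode_map)) {
    b0 <- dm[[s]]
    b1 <- collapse_duplicates(b0)
    b2 <- filter_short(b1, min_len)
    samples[[s]] <- b2
    rows[[s]] <- data.frame(sample = s, demultiplexed = nrow(b0),
                            after_dedup = nrow(b1), after_length = nrow(b2))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(samples = samples, summary = summary,
       n_unassigned = nrow(dm$unassigned))
}
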