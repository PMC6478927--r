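#' Reference genome container
#'
#' A `genome_ref` holds one upper-case A/C/G/T string per contig, together
#' with contig lengths. All pipeline coordinates are 0-based half-open
#' against these sequences.
#'
#' @param sequences named character vector of nucleotide strings.
#' @return An object of class `genome_ref` with elements `seq` (named
#'   character) and `len` (named integer).
#' @export
genome_ref <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("contig names must be present and unique")
  seqs <- chartr("u", "T", chartr("U", "T", toupper(sequences)))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("non-ACGT base in contig(s): ", paste(names(seqs)[bad], collapse = ", "))
  structure(
    list(seq = seqs, len = stats::setNames(nchar(seqs), names(seqs))),
    class = "genome_ref"
  )
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("genome_ref:", length(x$seq), "contig(s),",
      format(sum(x$len), big.mark = ","), "nt total\n")
  invisible(x)
}

#' Read a FASTA reference
#'
#' Sequences are upper-cased and U is mapped to T; any other non-ACGT base
#' is an error (the mutation caller needs an unambiguous reference).
#'
#' @param path FASTA file.
#' @return A [genome_ref()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path, "': ",
                                          conditionMessage(e)))
  if (length(ss) == 0) stop("FASTA file '", path, "' contains no sequences")
  nm <- sub("\\s.*$", "", names(ss))
  genome_ref(stats::setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#' @param genome a [genome_ref()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

#' Extract genome sequence over a 0-based half-open window
#'
#' @param genome a [genome_ref()].
#' @param contig contig name.
#' @param start,end 0-based half-open bounds.
#' @param strand `"+"` returns the forward string; `"-"` its reverse
#'   complement (transcript sense).
#' @return A single character string.
#' @export
genome_seq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome$seq)) stop("unknown contig: ", contig)
  if (start < 0 || end > genome$len[[contig]] || start >= end)
    stop("window [", start, ",", end, ") out of bounds on ", contig)
  s <- substr(genome$seq[[contig]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

#' Reverse-complement nucleotide strings
#' @param x character vector of A/C/G/T strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# single-base lookup, vectorised over 0-based positions on one contig
genome_base <- function(genome, contig, pos) {
  n <- genome$len[[contig]]
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 0L & pos < n
  if (any(ok))
    out[ok] <- substring(genome$seq[[contig]], pos[ok] + 1L, pos[ok] + 1L)
  out
}
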