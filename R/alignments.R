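#' Ungapped alignment container
#'
#' Alignments are stored as two data frames: `reads` with one row per
#' alignment (`read_id`, `contig`, `strand`, `start` 0-based leftmost,
#' `span` aligned length, `is_unique` dedup flag) and `mm` with one row per
#' mismatch (`aln` row index into `reads`, `offset` 0-based genomic offset
#' within the span, `ref`/`alt` bases in forward-genome sense).
#'
#' @param reads data frame as described above.
#' @param mm mismatch data frame as described above (may have zero rows).
#' @return An object of class `clip_alignments`.
#' @export
clip_alignments <- function(reads, mm = empty_mm()) {
  stopifnot(all(c("read_id", "contig", "strand", "start", "span",
                  "is_unique") %in% names(reads)))
  if (nrow(mm) && (any(mm$offset < 0L) ||
                   any(mm$offset >= reads$span[mm$aln])))
    stop("mismatch offset outside aligned span")
  structure(list(reads = reads, mm = mm), class = "clip_alignments")
}

empty_mm <- function() {
  data.frame(aln = integer(0), offset = integer(0),
             ref = character(0), alt = character(0))
}

#' @export
print.clip_alignments <- function(x, ...) {
  cat("clip_alignments:", nrow(x$reads), "record(s),",
      nrow(x$mm), "mismatch(es)\n")
  invisible(x)
}

#' Number of alignment records
#' @param aln a [clip_alignments()] object.
#' @return Integer count.
#' @export
n_alignments <- function(aln) nrow(aln$reads)

#' Read ungapped alignments from a SAM file
#'
#' Consumes the minimal SAM dialect the simulator emits: single-end,
#' primary, ungapped records (`CIGAR` of the form `<n>M`). Mismatches are
#' reconstructed by comparing `SEQ` (stored forward-genome sense, per SAM
#' convention) against the reference, so the `MD`/`NM` tags are not needed.
#' Unmapped, secondary/supplementary and indel- or clip-containing records
#' are skipped; their count is reported via a warning (or an error when
#' `allow_skips = FALSE`).
#'
#' @param path SAM file.
#' @param genome a [genome_ref()]; every mapped record must reference one of
#'   its contigs.
#' @param allow_skips if `FALSE`, any unsupported record is an error.
#' @return A [clip_alignments()] object; all records have
#'   `is_unique = TRUE` (dedup status is decided upstream by preprocessing).
#' @export
read_alignments <- function(path, genome, allow_skips = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@") & nzchar(ln)]
  if (length(ln) == 0)
    return(clip_alignments(empty_reads()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11)) stop("malformed SAM record at line ", which(nf < 11)[1])
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos1 <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  seqs <- toupper(vapply(f, `[[`, "", 10L))

  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 2304L) > 0L   # 0x100 | 0x800
  ungapped <- grepl("^[0-9]+M$", cigar)
  keep <- !unmapped & !secondary & ungapped
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    msg <- paste0(n_skip, " unsupported SAM record(s) skipped ",
                  "(unmapped/secondary/non-<n>M CIGAR)")
    if (!allow_skips) stop(msg)
    warning(msg)
  }
  if (!any(keep)) return(clip_alignments(empty_reads()))

  f <- f[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos1 <- pos1[keep]; seqs <- seqs[keep]
  unknown <- !rname %in% names(genome$seq)
  if (any(unknown)) stop("unknown contig in SAM: ", unique(rname[unknown])[1])

  span <- nchar(seqs)
  start <- pos1 - 1L
  over <- start < 0L | start + span > genome$len[rname]
  if (any(over)) stop("alignment outside contig bounds at record ", which(over)[1])
  reads <- data.frame(
    read_id = vapply(f, `[[`, "", 1L),
    contig = rname,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    start = start,
    span = span,
    is_unique = TRUE,
    stringsAsFactors = FALSE
  )
  clip_alignments(reads, find_mismatches(reads, seqs, genome))
}

empty_reads <- function() {
  data.frame(read_id = character(0), contig = character(0),
             strand = character(0), start = integer(0), span = integer(0),
             is_unique = logical(0), stringsAsFactors = FALSE)
}

# compare forward-genome-sense read strings to the reference
find_mismatches <- function(reads, seqs, genome) {
  refs <- ref_strings(reads, genome)
  diff <- which(refs != seqs)
  pieces <- lapply(diff, function(i) {
    rb <- strsplit(refs[i], "", fixed = TRUE)[[1]]
    qb <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    d <- which(rb != qb)
    data.frame(aln = i, offset = d - 1L, ref = rb[d], alt = qb[d])
  })
  if (length(pieces) == 0) empty_mm() else do.call(rbind, pieces)
}

# vectorised reference substring per alignment record
ref_strings <- function(reads, genome) {
  refs <- character(nrow(reads))
  for (ctg in unique(reads$contig)) {
    w <- which(reads$contig == ctg)
    refs[w] <- substring(genome$seq[[ctg]], reads$start[w] + 1L,
                         reads$start[w] + reads$span[w])
  }
  refs
}

#' Write alignments as SAM
#'
#' Emits a minimal headered SAM: `@SQ` lines from the genome plus one
#' ungapped record per read. `SEQ` is the reference substring with the
#' record's mismatches applied (forward-genome sense).
#'
#' @param aln a [clip_alignments()] object.
#' @param genome a [genome_ref()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$len),
                   as.integer(genome$len)))
  r <- aln$reads
  seqs <- ref_strings(r, genome)
  if (nrow(aln$mm)) {
    for (j in seq_len(nrow(aln$mm))) {
      i <- aln$mm$aln[j]; o <- aln$mm$offset[j]
      substr(seqs[i], o + 1L, o + 1L) <- aln$mm$alt[j]
    }
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                 r$read_id, ifelse(r$strand == "-", 16L, 0L), r$contig,
                 r$start + 1L, r$span, seqs, strrep("I", r$span))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Restrict alignments to a set of read ids
#'
#' Used after preprocessing to keep only deduplicated survivors; retained
#' records are marked `is_unique = TRUE`.
#'
#' @param aln a [clip_alignments()] object.
#' @param read_ids character vector of ids to keep.
#' @return A filtered [clip_alignments()] object.
#' @export
subset_alignments <- function(aln, read_ids) {
  keep <- which(aln$reads$read_id %in% read_ids)
  reads <- aln$reads[keep, , drop = FALSE]
  reads$is_unique <- TRUE
  rownames(reads) <- NULL
  mm <- aln$mm[aln$mm$aln %in% keep, , drop = FALSE]
  mm$aln <- match(mm$aln, keep)
  rownames(mm) <- NULL
  clip_alignments(reads, mm)
}
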