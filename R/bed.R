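#' Write single-nucleotide sites as BED6+
#'
#' Each site becomes a 0-based half-open one-base interval
#' `[pos, pos + 1)`. Columns beyond `contig`/`pos`/`strand`/`name`/`score`
#' (e.g. `k`, `m`, `ratio`, `fdr`, `p`, `q`) are appended after the six BED
#' fields and recorded in a `#`-header so [read_sites_bed()] restores them
#' by name: `read_sites_bed(write_sites_bed(x))` is the identity.
#'
#' @param sites data frame with at least `contig`, `pos` (0-based), and
#'   `strand`; `name` and `score` are synthesised when absent.
#' @param path output file.
#' @param genome optional [genome_ref()] for bounds checking.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, genome = NULL) {
  stopifnot(all(c("contig", "pos", "strand") %in% names(sites)))
  if (!is.null(genome)) {
    if (any(sites$pos < 0L) ||
        any(sites$pos >= genome$len[sites$contig]))
      stop("site position out of contig bounds")
  }
  extra <- setdiff(names(sites), c("contig", "pos", "strand", "name", "score"))
  hdr <- paste(c("#contig", "start", "end", "name", "score", "strand", extra),
               collapse = "\t")
  nm <- if ("name" %in% names(sites)) sites$name else
    sprintf("site_%d", seq_len(nrow(sites)))
  sc <- if ("score" %in% names(sites)) sites$score else rep(0, nrow(sites))
  cols <- c(list(sites$contig, sites$pos, sites$pos + 1L, nm, sc, sites$strand),
            lapply(extra, function(e) sites[[e]]))
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED6+ site file written by [write_sites_bed()]
#'
#' @param path BED file.
#' @return A sites data frame (`contig`, `pos`, `strand`, `name`, `score`,
#'   plus any extra statistic columns named in the header).
#' @export
read_sites_bed <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#") & nzchar(ln)]
  cn <- if (length(hdr)) {
    sub("^#", "", strsplit(hdr[1], "\t", fixed = TRUE)[[1]])
  } else c("contig", "start", "end", "name", "score", "strand")
  if (length(body) == 0) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), name = character(0),
                      score = numeric(0))
    for (e in setdiff(cn, c("contig", "start", "end", "name", "score", "strand")))
      out[[e]] <- numeric(0)
    return(out)
  }
  d <- utils::read.table(text = body, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character")
  names(d) <- cn[seq_len(ncol(d))]
  # numeric-looking columns become numbers; base letters (A/C/G/T) survive
  for (j in seq_along(d)) {
    num <- suppressWarnings(as.numeric(d[[j]]))
    if (!anyNA(num)) {
      d[[j]] <- if (all(grepl("^-?[0-9]+$", d[[j]]))) as.integer(d[[j]])
                else num
    }
  }
  if (any(d$end != d$start + 1L))
    stop("non single-nucleotide interval in site BED")
  out <- data.frame(contig = as.character(d$contig), pos = as.integer(d$start),
                    strand = as.character(d$strand), name = as.character(d$name),
                    score = d$score, stringsAsFactors = FALSE)
  for (e in setdiff(cn, c("contig", "start", "end", "name", "score", "strand")))
    out[[e]] <- d[[e]]
  out
}

#' Read an interval mask (BED or minimal VCF)
#'
#' BED input is taken as 0-based half-open. Files whose name ends in
#' `.vcf` (or whose first data line has a `#CHROM` style VCF header) are
#' read as minimal VCF: 1-based positions converted to 0-based
#' single-nucleotide intervals.
#'
#' @param path BED or VCF file.
#' @param genome optional [genome_ref()] for contig validation.
#' @return An interval data frame (`contig`, `start`, `end`, `strand`,
#'   `label`), 0-based half-open.
#' @export
read_interval_mask <- function(path, genome = NULL) {
  ln <- readLines(path)
  is_vcf <- grepl("\\.vcf$", path) || any(startsWith(ln, "##fileformat=VCF"))
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  d <- utils::read.table(text = ln, sep = "\t", stringsAsFactors = FALSE)
  if (is_vcf) {
    out <- data.frame(contig = as.character(d[[1]]),
                      start = as.integer(d[[2]]) - 1L,
                      end = as.integer(d[[2]]),
                      strand = "*",
                      label = if (ncol(d) >= 3) as.character(d[[3]]) else ".",
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(contig = as.character(d[[1]]),
                      start = as.integer(d[[2]]),
                      end = as.integer(d[[3]]),
                      strand = if (ncol(d) >= 6) as.character(d[[6]]) else "*",
                      label = if (ncol(d) >= 4) as.character(d[[4]]) else ".",
                      stringsAsFactors = FALSE)
  }
  if (any(out$start >= out$end)) stop("interval with start >= end in ", path)
  if (!is.null(genome) && any(!out$contig %in% names(genome$seq)))
    stop("interval on unknown contig in ", path)
  out
}

#' Write per-strand unique-tag coverage as bedGraph
#'
#' Adjacent equal-coverage positions are merged into runs; zero-coverage
#' runs are omitted. One track section per strand.
#'
#' @param tally a [site_tally()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(tally, path) {
  out <- character(0)
  for (strand in c("+", "-")) {
    out <- c(out, sprintf("track type=bedGraph name=\"coverage_%s\"",
                          ifelse(strand == "+", "fwd", "rev")))
    for (contig in names(tally$k)) {
      v <- tally$k[[contig]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values > 0
      if (any(keep))
        out <- c(out, sprintf("%s\t%d\t%d\t%d", contig,
                              starts[keep], ends[keep], r$values[keep]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph written by [write_coverage_bedgraph()]
#'
#' @param path bedGraph file.
#' @return Data frame (`contig`, `start`, `end`, `value`, `strand`).
#' @export
read_bedgraph <- function(path) {
  ln <- readLines(path)
  strand <- "+"
  rows <- list()
  for (l in ln) {
    if (startsWith(l, "track")) {
      strand <- if (grepl("_rev", l)) "-" else "+"
      next
    }
    if (!nzchar(l)) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      contig = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
      value = as.numeric(f[4]), strand = strand, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), value = numeric(0),
                      strand = character(0)))
  do.call(rbind, rows)
}
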