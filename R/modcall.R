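#' Remove candidate sites at known SNP positions
#'
#' Any candidate whose position falls inside the mask (same contig; the
#' mask's strand is ignored, as genomic SNPs confound either strand) is
#' dropped; the number removed is reported via an attribute.
#'
#' @param sites site data frame (`contig`, `pos`, ...).
#' @param snp_mask interval data frame from [read_interval_mask()]
#'   (0-based half-open).
#' @return The filtered site data frame, with attribute `n_masked`.
#' @export
mask_known_snps <- function(sites, snp_mask) {
  if (nrow(sites) == 0 || nrow(snp_mask) == 0) {
    attr(sites, "n_masked") <- 0L
    return(sites)
  }
  hit <- rep(FALSE, nrow(sites))
  for (ctg in unique(sites$contig)) {
    mk <- snp_mask[snp_mask$contig == ctg, , drop = FALSE]
    if (nrow(mk) == 0) next
    w <- which(sites$contig == ctg)
    ir <- IRanges::IRanges(mk$start + 1L, mk$end)
    hit[w] <- IRanges::countOverlaps(
      IRanges::IRanges(sites$pos[w] + 1L, width = 1L), ir) > 0L
  }
  out <- sites[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_masked") <- sum(hit)
  out
}

# transcript-sense base at an offset from a site (offset in transcript nt)
tx_base_at <- function(genome, contig, pos, strand, offset = 0L) {
  gpos <- ifelse(strand == "+", pos + offset, pos - offset)
  b <- character(length(pos))
  for (ctg in unique(contig)) {
    w <- which(contig == ctg)
    b[w] <- genome_base(genome, ctg, gpos[w])
  }
  ifelse(strand == "-", comp_base(b), b)
}

mod_site_frame <- function(contig, pos, strand, evidence, stat, value) {
  n <- length(pos)
  data.frame(contig = contig, pos = as.integer(pos), strand = strand,
             evidence = rep_len(evidence, n), stat = rep_len(stat, n),
             value = value,
             fp_start = as.integer(pos) - 5L, fp_end = as.integer(pos) + 6L,
             stringsAsFactors = FALSE)
}

#' Call m6A residues from CIMS candidates (miCLIP rules)
#'
#' Retains C>T substitution positions with `m/k <= max_ratio` (boundary
#' inclusive) whose transcript-strand -1 base is an adenosine, and emits
#' the m6A at that adenosine (the substitution sits at the +1 position of
#' the methylated A). An optional permutation-FDR cut can be applied on
#' top; the pipeline enables it, the bare rule does not.
#'
#' @param cims CIMS data frame from [call_cims()] (SNP-masked).
#' @param genome a [genome_ref()].
#' @param max_ratio maximum `m/k` (default 0.5, inclusive).
#' @param fdr optional FDR cut (inclusive); `NULL` disables it.
#' @return `ModSite` data frame: `contig`, `pos` (the adenosine),
#'   `strand`, `evidence = "CIMS"`, source statistic, and the
#'   `[pos - 5, pos + 6)` footprint window.
#' @export
call_m6a_from_cims <- function(cims, genome, max_ratio = 0.5, fdr = NULL) {
  keep <- cims$ref == "C" & cims$alt == "T" & cims$ratio <= max_ratio
  if (!is.null(fdr)) keep <- keep & cims$fdr <= fdr
  s <- cims[keep, , drop = FALSE]
  if (nrow(s) == 0)
    return(mod_site_frame(character(0), integer(0), character(0),
                          character(0), character(0), numeric(0)))
  up <- tx_base_at(genome, s$contig, s$pos, s$strand, -1L)
  s <- s[!is.na(up) & up == "A", , drop = FALSE]
  if (nrow(s) == 0)
    return(mod_site_frame(character(0), integer(0), character(0),
                          character(0), character(0), numeric(0)))
  a_pos <- ifelse(s$strand == "+", s$pos - 1L, s$pos + 1L)
  out <- mod_site_frame(s$contig, a_pos, s$strand, "CIMS", "ratio", s$ratio)
  stopifnot(all(tx_base_at(genome, out$contig, out$pos, out$strand) == "A"))
  out
}

#' Call m6A residues from CITS candidates
#'
#' Retains significant truncation sites (BH `q <= alpha` by default, raw
#' `p <= alpha` with `use_raw_p`) that sit at or immediately beside an
#' adenosine on the transcript strand; the m6A is assigned to that A,
#' preferring the site itself, then -1, then +1.
#'
#' @param cits CITS data frame from [call_cits()].
#' @param genome a [genome_ref()].
#' @param alpha significance cut (inclusive; default 0.05).
#' @param use_raw_p threshold the raw binomial p instead of BH q.
#' @return `ModSite` data frame (`evidence = "CITS"`).
#' @export
call_m6a_from_cits <- function(cits, genome, alpha = 0.05,
                               use_raw_p = FALSE) {
  val <- if (use_raw_p) cits$p else cits$q
  s <- cits[val <= alpha, , drop = FALSE]
  if (nrow(s) == 0)
    return(mod_site_frame(character(0), integer(0), character(0),
                          character(0), character(0), numeric(0)))
  b0 <- tx_base_at(genome, s$contig, s$pos, s$strand, 0L)
  bm <- tx_base_at(genome, s$contig, s$pos, s$strand, -1L)
  bp <- tx_base_at(genome, s$contig, s$pos, s$strand, +1L)
  off <- ifelse(!is.na(b0) & b0 == "A", 0L,
                ifelse(!is.na(bm) & bm == "A", -1L,
                       ifelse(!is.na(bp) & bp == "A", 1L, NA_integer_)))
  keep <- !is.na(off)
  s <- s[keep, , drop = FALSE]; off <- off[keep]
  if (nrow(s) == 0)
    return(mod_site_frame(character(0), integer(0), character(0),
                          character(0), character(0), numeric(0)))
  a_pos <- ifelse(s$strand == "+", s$pos + off, s$pos - off)
  out <- mod_site_frame(s$contig, a_pos, s$strand, "CITS",
                        if (use_raw_p) "p" else "q",
                        if (use_raw_p) s$p else s$q)
  out <- out[!duplicated(paste(out$contig, out$strand, out$pos)), ,
             drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(tx_base_at(genome, out$contig, out$pos, out$strand) == "A"))
  out
}

#' Call reader-binding footprints from CIMS and CITS candidates
#'
#' The CIMS branch keeps any substitution position with permutation
#' `FDR <= fdr` (no base-context restriction); the CITS branch applies
#' the same adenosine-neighbor procedure as [call_m6a_from_cits()]
#' (disable with `cits_require_a = FALSE`). Every retained site carries
#' its +/-5 nt footprint window.
#'
#' @param cims,cits candidate data frames (SNP-masked).
#' @param genome a [genome_ref()].
#' @param fdr CIMS FDR cut (inclusive; default 0.1).
#' @param alpha CITS significance cut (inclusive; default 0.05).
#' @param use_raw_p threshold raw CITS p instead of BH q.
#' @param cits_require_a keep the adenosine-neighbor filter on the CITS
#'   branch (default `TRUE`).
#' @return `ModSite` data frame with `evidence` in `{"CIMS", "CITS"}`;
#'   footprint windows `[pos - 5, pos + 6)` half-open.
#' @export
call_reader_footprints <- function(cims, cits, genome, fdr = 0.1,
                                   alpha = 0.05, use_raw_p = FALSE,
                                   cits_require_a = TRUE) {
  s <- cims[cims$fdr <= fdr, , drop = FALSE]
  out_cims <- mod_site_frame(s$contig, s$pos, s$strand, "CIMS", "fdr", s$fdr)
  if (cits_require_a) {
    out_cits <- call_m6a_from_cits(cits, genome, alpha, use_raw_p)
  } else {
    val <- if (use_raw_p) cits$p else cits$q
    sc <- cits[val <= alpha, , drop = FALSE]
    out_cits <- mod_site_frame(sc$contig, sc$pos, sc$strand, "CITS",
                               if (use_raw_p) "p" else "q",
                               if (use_raw_p) sc$p else sc$q)
  }
  out <- rbind(out_cims, out_cits)
  out <- out[order(out$contig, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge CIMS- and CITS-based m6A calls into one site set
#'
#' Sites supported by both evidence classes collapse to one row with
#' `evidence = "CIMS+CITS"`.
#'
#' @param cims_m6a,cits_m6a `ModSite` frames from the two callers.
#' @return A combined `ModSite` data frame, one row per position.
#' @export
combine_m6a_calls <- function(cims_m6a, cits_m6a) {
  all <- rbind(cims_m6a, cits_m6a)
  if (nrow(all) == 0) return(all)
  key <- paste(all$contig, all$strand, all$pos)
  dup <- key[duplicated(key)]
  all$evidence[key %in% dup] <- "CIMS+CITS"
  out <- all[!duplicated(key), , drop = FALSE]
  out <- out[order(out$contig, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
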