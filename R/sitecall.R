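#' Per-position tallies of coverage, substitutions and truncations
#'
#' For every (contig, strand, position): `k` = unique-tag coverage (each
#' deduplicated read counted once per covered position), `m` = unique tags
#' carrying a given substitution there (transcript-strand sense), and
#' `t` = unique tags whose inferred cross-link site is the position. The
#' cross-link site is the nucleotide immediately 5' of the read start on
#' the transcript strand (read start - 1), the standard iCLIP
#' cDNA-truncation geometry; cross-links falling off the contig are
#' dropped with a warning.
#'
#' @param aln a [clip_alignments()] object; records must already be
#'   deduplicated (`is_unique`).
#' @param genome a [genome_ref()]; every recorded mismatch must agree with
#'   the reference base, otherwise a data-integrity error is raised.
#' @return A `site_tally` object: per-contig/strand integer vectors `k`
#'   and `t`, the aggregated substitution table `m`, the per-event table
#'   `mm_events` (needed by the permutation null), and `lib_size`.
#' @export
tally_alignments <- function(aln, genome) {
  r <- aln$reads
  if (nrow(r) && !all(r$is_unique))
    stop("tally_alignments expects deduplicated (is_unique) records")
  k <- t <- list()
  n_dropped_xl <- 0L
  for (ctg in names(genome$seq)) {
    len <- genome$len[[ctg]]
    k[[ctg]] <- list(); t[[ctg]] <- list()
    for (strand in c("+", "-")) {
      w <- which(r$contig == ctg & r$strand == strand)
      if (length(w) == 0) {
        k[[ctg]][[strand]] <- integer(len)
        t[[ctg]][[strand]] <- integer(len)
        next
      }
      cov <- IRanges::coverage(
        IRanges::IRanges(start = r$start[w] + 1L, width = r$span[w]),
        width = len)
      k[[ctg]][[strand]] <- as.integer(cov)
      xl <- if (strand == "+") r$start[w] - 1L else r$start[w] + r$span[w]
      ok <- xl >= 0L & xl < len
      n_dropped_xl <- n_dropped_xl + sum(!ok)
      t[[ctg]][[strand]] <- tabulate(xl[ok] + 1L, nbins = len)
    }
  }
  if (n_dropped_xl > 0)
    warning(n_dropped_xl, " cross-link position(s) off contig dropped")

  mm <- aln$mm
  if (nrow(mm)) {
    pos <- r$start[mm$aln] + mm$offset
    ctg <- r$contig[mm$aln]
    strand <- r$strand[mm$aln]
    gb <- character(nrow(mm))
    for (cc in unique(ctg)) {
      w <- which(ctg == cc)
      gb[w] <- genome_base(genome, cc, pos[w])
    }
    if (any(gb != mm$ref))
      stop("data-integrity error: mismatch ref base disagrees with genome at ",
           ctg[gb != mm$ref][1], ":", pos[gb != mm$ref][1])
    neg <- strand == "-"
    mm_events <- data.frame(
      contig = ctg, strand = strand, pos = pos,
      ref = ifelse(neg, comp_base(mm$ref), mm$ref),
      alt = ifelse(neg, comp_base(mm$alt), mm$alt),
      read_start = r$start[mm$aln], read_span = r$span[mm$aln],
      stringsAsFactors = FALSE)
    key <- paste(mm_events$contig, mm_events$strand, mm_events$pos,
                 mm_events$ref, mm_events$alt, sep = "\r")
    agg <- table(key)
    parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    m <- data.frame(contig = parts[, 1], strand = parts[, 2],
                    pos = as.integer(parts[, 3]), ref = parts[, 4],
                    alt = parts[, 5], m = as.integer(agg),
                    stringsAsFactors = FALSE)
    m <- m[order(m$contig, m$strand, m$pos), ]
    rownames(m) <- NULL
  } else {
    mm_events <- data.frame(contig = character(0), strand = character(0),
                            pos = integer(0), ref = character(0),
                            alt = character(0), read_start = integer(0),
                            read_span = integer(0))
    m <- data.frame(contig = character(0), strand = character(0),
                    pos = integer(0), ref = character(0),
                    alt = character(0), m = integer(0))
  }
  structure(list(k = k, t = t, m = m, mm_events = mm_events,
                 lib_size = nrow(r)),
            class = "site_tally")
}

#' @export
print.site_tally <- function(x, ...) {
  cat("site_tally:", x$lib_size, "unique tags,",
      nrow(x$m), "substituted position(s),",
      sum(vapply(x$t, function(s) sum(vapply(s, sum, numeric(1))),
                 numeric(1))), "cross-link events\n")
  invisible(x)
}

# coverage k at site rows (vectors pos 0-based)
tally_k_at <- function(tally, contig, strand, pos) {
  out <- integer(length(pos))
  key <- paste(contig, strand)
  for (kk in unique(key)) {
    w <- which(key == kk)
    out[w] <- tally$k[[contig[w[1]]]][[strand[w[1]]]][pos[w] + 1L]
  }
  out
}

#' Call cross-linking-induced mutation sites (CIMS) with permutation FDR
#'
#' Candidates are positions with at least one substitution of `sub_type`
#' (transcript sense). The null keeps every read in place and, in each of
#' `n_perm` rounds, relocates each observed substitution event uniformly
#' within its own read's aligned span, preserving coverage structure and
#' per-read mutation counts. For a candidate with coverage `k` and count
#' `m`, FDR = (mean over rounds of the number of null positions with
#' coverage `k` and null count >= `m`) divided by the number of observed
#' positions with coverage `k` and count >= `m`, capped at 1 and
#' monotonized to be non-increasing in `m` within each `k` stratum.
#'
#' @param tally a `site_tally` from [tally_alignments()].
#' @param sub_type substitution to test, e.g. `"C>T"` (transcript sense).
#' @param n_perm number of permutation rounds (>= 1).
#' @param seed integer seed; the call is deterministic given the seed.
#' @return Data frame of CIMS candidates: `contig`, `pos`, `strand`,
#'   `ref`, `alt`, `k`, `m`, `ratio`, `fdr`, ordered by position.
#' @export
call_cims <- function(tally, sub_type = "C>T", n_perm = 10L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  parts <- strsplit(sub_type, ">", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("sub_type must look like 'C>T'")
  cand <- tally$m[tally$m$ref == parts[1] & tally$m$alt == parts[2], ,
                  drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), ref = character(0),
                      alt = character(0), k = integer(0), m = integer(0),
                      ratio = numeric(0), fdr = numeric(0)))
  }
  cand$k <- tally_k_at(tally, cand$contig, cand$strand, cand$pos)
  cand$ratio <- cand$m / cand$k

  ev <- tally$mm_events
  ev <- ev[ev$ref == parts[1] & ev$alt == parts[2], , drop = FALSE]
  # observed strata: for each k, the sorted vector of candidate m values
  obs_by_k <- split(cand$m, cand$k)

  null_sum <- stats::setNames(
    lapply(obs_by_k, function(v) numeric(length(unique(sort(v))))),
    names(obs_by_k))
  mvals_by_k <- lapply(obs_by_k, function(v) sort(unique(v)))

  with_seed(seed, {
    strand_key <- paste(ev$contig, ev$strand, sep = "\r")
    for (b in seq_len(n_perm)) {
      npos <- ev$read_start +
        floor(stats::runif(nrow(ev)) * ev$read_span)
      key <- paste(strand_key, npos, sep = "\r")
      tab <- table(key)
      parts3 <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
      nk <- tally_k_at(tally, parts3[, 1], parts3[, 2],
                       as.integer(parts3[, 3]))
      nm <- as.integer(tab)
      for (ks in names(mvals_by_k)) {
        kk <- as.integer(ks)
        vm <- nm[nk == kk]
        if (length(vm) == 0) next
        null_sum[[ks]] <- null_sum[[ks]] +
          vapply(mvals_by_k[[ks]], function(m0) sum(vm >= m0), numeric(1))
      }
    }
  })

  fdr_by_k <- lapply(names(mvals_by_k), function(ks) {
    mv <- mvals_by_k[[ks]]
    obs_ge <- vapply(mv, function(m0) sum(obs_by_k[[ks]] >= m0), numeric(1))
    raw <- (null_sum[[ks]] / n_perm) / obs_ge
    stats::setNames(pmin(cummin(pmin(raw, 1)), 1), mv)  # non-increasing in m
  })
  names(fdr_by_k) <- names(mvals_by_k)
  cand$fdr <- mapply(function(k, m) fdr_by_k[[as.character(k)]][[as.character(m)]],
                     cand$k, cand$m)
  cand <- cand[order(cand$contig, cand$strand, cand$pos), ]
  rownames(cand) <- NULL
  cand[c("contig", "pos", "strand", "ref", "alt", "k", "m", "ratio", "fdr")]
}

#' Call cross-linking-induced truncation sites (CITS)
#'
#' Clusters are maximal runs of positions with coverage `k >= 1` per
#' contig and strand. Within a cluster of covered length `L` holding `n`
#' truncation events in total, each position with `t >= 1` is tested
#' against Binomial(`n`, 1/`L`): `p = P[X >= t]`. `q` is the
#' Benjamini-Hochberg adjustment over all tested positions genome-wide,
#' with ties broken by position order for determinism.
#'
#' @param tally a `site_tally` from [tally_alignments()].
#' @return Data frame of tested positions: `contig`, `pos`, `strand`, `t`,
#'   `L` (cluster length), `n` (cluster truncations), `p`, `q`.
#' @export
call_cits <- function(tally) {
  rows <- list()
  for (ctg in names(tally$k)) {
    for (strand in c("+", "-")) {
      kv <- tally$k[[ctg]][[strand]]
      tv <- tally$t[[ctg]][[strand]]
      r <- rle(kv >= 1L)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L            # 1-based
      runs <- which(r$values)
      if (length(runs) == 0) next
      ct <- cumsum(tv)
      for (i in runs) {
        a <- starts[i]; b <- ends[i]
        L <- b - a + 1L
        n <- ct[b] - (if (a > 1L) ct[a - 1L] else 0L)
        if (n == 0L) next
        w <- which(tv[a:b] >= 1L) + a - 1L
        if (length(w) == 0) next
        tt <- tv[w]
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, pos = w - 1L, strand = strand, t = tt, L = L, n = n,
          p = stats::pbinom(tt - 1L, n, 1 / L, lower.tail = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), t = integer(0), L = integer(0),
                      n = integer(0), p = numeric(0), q = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$strand, out$pos), ]
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values (monotone step-up, order-preserving).
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
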