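#' Overlap two single-nucleotide site sets
#'
#' A site in A overlaps B if some B site lies within `tolerance` nt on the
#' same contig and strand; matching is greedy nearest-first and
#' one-to-one, so each site is counted once and the overlap count is
#' symmetric in its arguments.
#'
#' @param a,b site data frames (`contig`, `pos`, `strand`).
#' @param tolerance maximum pairing distance in nt (default 5, the
#'   footprint flank).
#' @return A `venn_result` list: `n_a_only`, `n_b_only`, `n_overlap`,
#'   `tolerance`, and the matched `pairs` data frame.
#' @export
overlap_sites <- function(a, b, tolerance = 5L) {
  pairs <- list()
  key_a <- paste(a$contig, a$strand)
  key_b <- paste(b$contig, b$strand)
  for (grp in intersect(unique(key_a), unique(key_b))) {
    ia <- which(key_a == grp); ib <- which(key_b == grp)
    bp <- b$pos[ib]; ord <- order(bp); ib <- ib[ord]; bp <- bp[ord]
    for (i in ia) {
      lo <- findInterval(a$pos[i] - tolerance - 1L, bp) + 1L
      hi <- findInterval(a$pos[i] + tolerance, bp)
      if (lo <= hi)
        pairs[[length(pairs) + 1L]] <- data.frame(
          ai = i, bi = ib[lo:hi], d = abs(a$pos[i] - bp[lo:hi]))
    }
  }
  matched <- data.frame(ai = integer(0), bi = integer(0), d = integer(0))
  if (length(pairs)) {
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[order(pairs$d, pairs$ai, pairs$bi), , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    keep <- logical(nrow(pairs))
    for (j in seq_len(nrow(pairs))) {
      if (!used_a[pairs$ai[j]] && !used_b[pairs$bi[j]]) {
        keep[j] <- TRUE
        used_a[pairs$ai[j]] <- TRUE
        used_b[pairs$bi[j]] <- TRUE
      }
    }
    matched <- pairs[keep, , drop = FALSE]
    rownames(matched) <- NULL
  }
  structure(list(n_a_only = nrow(a) - nrow(matched),
                 n_b_only = nrow(b) - nrow(matched),
                 n_overlap = nrow(matched),
                 tolerance = tolerance, pairs = matched),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("venn_result (tol %d nt): A-only %d | overlap %d | B-only %d\n",
              x$tolerance, x$n_a_only, x$n_overlap, x$n_b_only))
  invisible(x)
}

# library-size scale factor: counts per million unique tags
cpm_factor <- function(tally) 1e6 / max(tally$lib_size, 1L)

#' Metagene profile of unique-tag coverage around anchor positions
#'
#' For each anchor the strand-oriented coverage vector over offsets
#' `[-W, W]` is extracted (minus-strand anchors reversed so offsets run
#' 5' to 3' on the transcript); vectors are normalized and averaged.
#' Anchors whose window leaves the contig are dropped with a warning.
#'
#' @param tally a `site_tally`.
#' @param anchors site data frame (`contig`, `pos`, `strand`).
#' @param halfwidth window half-width W in nt (default 100).
#' @param normalization `"cpm"` (counts per million unique tags, default),
#'   `"none"` (raw coverage), or `"per_anchor"` (each vector sums to 1).
#' @return A `metagene_profile` list: `offsets`, `intensity`, `n_anchors`,
#'   `normalization`.
#' @export
metagene_profile <- function(tally, anchors, halfwidth = 100L,
                             normalization = c("cpm", "none", "per_anchor")) {
  normalization <- match.arg(normalization)
  if (nrow(anchors) == 0) stop("no anchors")
  W <- as.integer(halfwidth)
  acc <- numeric(2L * W + 1L)
  n_used <- 0L; n_dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    kv <- tally$k[[anchors$contig[i]]][[anchors$strand[i]]]
    p <- anchors$pos[i]
    if (p - W < 0L || p + W >= length(kv)) {
      n_dropped <- n_dropped + 1L
      next
    }
    v <- as.numeric(kv[(p - W):(p + W) + 1L])
    if (anchors$strand[i] == "-") v <- rev(v)
    if (normalization == "per_anchor") {
      if (sum(v) > 0) v <- v / sum(v)
    } else if (normalization == "cpm") {
      v <- v * cpm_factor(tally)
    }
    acc <- acc + v
    n_used <- n_used + 1L
  }
  if (n_dropped > 0)
    warning(n_dropped, " anchor(s) dropped at contig edges")
  if (n_used == 0) stop("no usable anchors")
  structure(list(offsets = -W:W, intensity = acc / n_used,
                 n_anchors = n_used, normalization = normalization),
            class = "metagene_profile")
}

#' Compare binding intensity at splice sites near vs not near m6A
#'
#' A splice site is "near" iff some m6A residue lies within `flank` nt on
#' the same contig and strand (boundary inclusive at exactly `flank`).
#' Per-site intensity is the mean unique-tag coverage over
#' `[pos - intensity_window, pos + intensity_window]` (library-scaled),
#' and the groups are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param splice_sites,m6a_sites site data frames (`contig`, `pos`,
#'   `strand`).
#' @param tally a `site_tally` of the binding library.
#' @param flank proximity threshold in nt (default 100, inclusive).
#' @param intensity_window intensity half-window in nt (default 10).
#' @return A `group_comparison` list: per-site table, group sizes, `U`,
#'   two-sided `p` (`NA` with a warning when a group is empty).
#' @export
splice_proximity_test <- function(splice_sites, m6a_sites, tally,
                                  flank = 100L, intensity_window = 10L) {
  if (nrow(splice_sites) == 0 || nrow(m6a_sites) == 0)
    stop("splice-site and m6A lists must be nonempty")
  d <- rep(Inf, nrow(splice_sites))
  key_s <- paste(splice_sites$contig, splice_sites$strand)
  key_m <- paste(m6a_sites$contig, m6a_sites$strand)
  for (grp in unique(key_s)) {
    w <- which(key_s == grp)
    mp <- sort(m6a_sites$pos[key_m == grp])
    if (length(mp) == 0) next
    for (i in w) {
      j <- findInterval(splice_sites$pos[i], mp)
      cand <- mp[pmax(1L, j):pmin(length(mp), j + 1L)]
      d[i] <- min(abs(splice_sites$pos[i] - cand))
    }
  }
  near <- d <= flank
  intensity <- numeric(nrow(splice_sites))
  for (i in seq_len(nrow(splice_sites))) {
    kv <- tally$k[[splice_sites$contig[i]]][[splice_sites$strand[i]]]
    lo <- max(0L, splice_sites$pos[i] - intensity_window)
    hi <- min(length(kv) - 1L, splice_sites$pos[i] + intensity_window)
    intensity[i] <- mean(kv[(lo:hi) + 1L]) * cpm_factor(tally)
  }
  tab <- data.frame(contig = splice_sites$contig, pos = splice_sites$pos,
                    strand = splice_sites$strand, dist_m6a = d, near = near,
                    intensity = intensity, stringsAsFactors = FALSE)
  if (all(near) || all(!near)) {
    warning("one proximity group is empty; p set to NA")
    return(structure(list(sites = tab, n_near = sum(near),
                          n_far = sum(!near), U = NA_real_, p = NA_real_),
                     class = "group_comparison"))
  }
  ts <- wilcoxon_rank_sum(intensity[near], intensity[!near], "two.sided")
  structure(list(sites = tab, n_near = sum(near), n_far = sum(!near),
                 U = ts$U, p = ts$p),
            class = "group_comparison")
}

#' IUPAC motif enrichment in footprint windows
#'
#' Foreground windows are the 21-nt transcript-sense sequences centered on
#' retained CIMS/CITS positions (`[-10, 10]`); windows running off a
#' contig are dropped with a warning. The per-window score is the number
#' of motif matches on the transcript strand. The background is, per
#' foreground window, `n_bg_per_fg` dinucleotide-preserving shuffles
#' (default) or coverage-agnostic genome-sampled windows, and enrichment
#' is a one-sided (foreground greater) Wilcoxon rank-sum test.
#'
#' @param footprints site data frame (`contig`, `pos`, `strand`).
#' @param genome a [genome_ref()].
#' @param motif IUPAC motif string (default `"RGAC"`; R = A/G).
#' @param n_bg_per_fg background windows per foreground window.
#' @param bg_mode `"shuffle"` or `"genome"`.
#' @param seed integer seed for the background generator.
#' @return An `enrichment_result` list: `motif`, `fg_scores`,
#'   `bg_scores`, `U`, `p`, `ratio` (mean fg / mean bg score).
#' @export
motif_enrichment <- function(footprints, genome, motif = "RGAC",
                             n_bg_per_fg = 10L,
                             bg_mode = c("shuffle", "genome"), seed = 1L) {
  bg_mode <- match.arg(bg_mode)
  half <- 10L
  wlen <- 2L * half + 1L
  fg <- character(0)
  n_dropped <- 0L
  for (i in seq_len(nrow(footprints))) {
    ctg <- footprints$contig[i]; p <- footprints$pos[i]
    if (p - half < 0L || p + half + 1L > genome$len[[ctg]]) {
      n_dropped <- n_dropped + 1L
      next
    }
    fg <- c(fg, genome_seq(genome, ctg, p - half, p + half + 1L,
                           footprints$strand[i]))
  }
  if (n_dropped > 0)
    warning(n_dropped, " window(s) dropped at contig edges")
  if (length(fg) == 0) stop("no usable foreground windows")
  bg <- with_seed(seed, {
    if (bg_mode == "shuffle") {
      unlist(lapply(fg, function(s)
        vapply(seq_len(n_bg_per_fg), function(j) dinuc_shuffle(s),
               character(1))))
    } else {
      ctgs <- sample(names(genome$seq), length(fg) * n_bg_per_fg, TRUE)
      starts <- floor(stats::runif(length(ctgs)) *
                        (genome$len[ctgs] - wlen + 1))
      strands <- sample(c("+", "-"), length(ctgs), TRUE)
      mapply(function(c, s, st) genome_seq(genome, c, s, s + wlen, st),
             ctgs, starts, strands, USE.NAMES = FALSE)
    }
  })
  fg_scores <- motif_score(fg, motif)
  bg_scores <- motif_score(bg, motif)
  ts <- wilcoxon_rank_sum(fg_scores, bg_scores, "greater")
  structure(list(motif = motif, fg_scores = fg_scores,
                 bg_scores = bg_scores, U = ts$U, p = ts$p,
                 ratio = mean(fg_scores) / max(mean(bg_scores), 1e-12)),
            class = "enrichment_result")
}

#' Count IUPAC motif matches per sequence window
#' @param windows character vector of A/C/G/T strings.
#' @param motif IUPAC motif string.
#' @return Integer match counts.
#' @export
motif_score <- function(windows, motif) {
  subj <- Biostrings::DNAStringSet(windows)
  Biostrings::vcountPattern(motif, subj, fixed = FALSE)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: returns a random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) composition, first and
#' last base as the input. Uses the caller's RNG stream.
#'
#' @param s a single A/C/G/T string.
#' @return A shuffled string.
#' @export
dinuc_shuffle <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(s)
  verts <- unique(ch)
  out_edges <- split(ch[-1], ch[-n])       # multiset of targets per vertex
  f <- ch[n]
  srcs <- setdiff(names(out_edges), f)
  repeat {
    last <- vapply(srcs, function(v) sample(out_edges[[v]], 1L), character(1))
    ok <- TRUE
    for (v in srcs) {                       # every vertex must reach f
      cur <- v; seen <- character(0)
      while (cur != f) {
        if (cur %in% seen || !(cur %in% srcs)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  seqs <- list()
  for (v in names(out_edges)) {
    e <- out_edges[[v]]
    if (v %in% srcs) {
      e <- e[-match(last[[v]], e)]
      seqs[[v]] <- c(if (length(e)) sample(e, length(e)), last[[v]])
    } else {
      seqs[[v]] <- if (length(e)) sample(e, length(e)) else character(0)
    }
  }
  res <- character(n)
  res[1] <- ch[1]
  cnt <- stats::setNames(rep(1L, length(verts)), verts)
  for (i in 2:n) {
    v <- res[i - 1]
    res[i] <- seqs[[v]][cnt[[v]]]
    cnt[[v]] <- cnt[[v]] + 1L
  }
  paste(res, collapse = "")
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when both groups are small (combined n <= 12) and
#' tie-free; otherwise the normal approximation with tie and continuity
#' correction. Degenerate all-tied input yields p = 1.
#'
#' @param x,y numeric vectors (nonempty).
#' @param alternative `"two.sided"`, `"less"` (x below y) or `"greater"`.
#' @return List with the Mann-Whitney `U` statistic (for `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = use_exact,
                       correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p = p)
}
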