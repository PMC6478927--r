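#' Simulation configuration
#'
#' Defaults describe the study conditions the planted-truth analyses run
#' under: a ~100 kb two-contig toy genome at 30x unique-tag coverage, 200
#' methylated adenosines on RGAC motifs, 200 reader footprints (70%
#' within 5 nt of an m6A), per-read cross-link mutation probability 0.3
#' and truncation probability 0.2, three-fold coverage enrichment at
#' cross-link sites, uniform background error 1e-3, heterozygous C>T SNP
#' confounders, and a 30% PCR duplication rate.
#'
#' @param ... overrides for any default field.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_contigs = 2L,
    contig_length = 50000L,
    gc = 0.5,
    genes_per_contig = 2L,
    n_m6a = 200L,
    n_footprints = 200L,
    overlap_fraction = 0.7,
    m6a_at_splice_edge = TRUE,
    site_spacing = 100L,
    n_sf_sites = 100L,
    sf_near_fraction = 0.5,
    depth = 30,
    site_enrichment = 3,
    read_len = c(30L, 50L),
    p_mut = 0.3,
    p_trunc = 0.2,
    bg_rate = 0.001,
    n_snp = 20L,
    snp_af = 0.5,
    pcr_rate = 0.3,
    barcodes = c(miCLIP = "ACGTG", NKAP = "TGCAT"),
    sample_sites = c(miCLIP = "m6a", NKAP = "anchors")
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  for (p in c("gc", "overlap_fraction", "p_mut", "p_trunc", "bg_rate",
              "snp_af", "pcr_rate", "sf_near_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0,1]")
  if (cfg$read_len[1] < 20L)
    stop("minimum read length must be >= 20 nt (shorter reads are discarded)")
  if (anyDuplicated(cfg$barcodes)) stop("duplicate barcode in barcode set")
  structure(cfg, class = "sim_config")
}

# evaluate code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# transcript-space helpers: t is a 0-based offset along the (spliced-out,
# intron-inclusive) pre-mRNA, i.e. along the gene span in 5'->3' order
tx_to_genomic <- function(gene, t) {
  if (gene$strand == "+") gene$start + t else gene$end - 1L - t
}
genomic_to_tx <- function(gene, g) {
  if (gene$strand == "+") g - gene$start else gene$end - 1L - g
}
tx_seq <- function(genome, gene) {
  genome_seq(genome, gene$contig, gene$start, gene$end, gene$strand)
}

#' Generate a toy genome and gene model
#'
#' Contigs are i.i.d. nucleotides at the requested GC fraction. Each contig
#' carries `genes_per_contig` multi-exon genes on alternating strands;
#' splice sites are the internal exon-edge positions. At least
#' `n_m6a + n_footprints` RGACT motif instances (transcript sense, mutual
#' genomic spacing >= `site_spacing` minus jitter) are written into gene
#' bodies so truth planting always has hosts; when `m6a_at_splice_edge` is
#' set, the first motif's adenosine is written exactly at a splice site,
#' the configuration of the worked pri-miR-25 example.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return `list(genome, model)` where `model` is a `gene_model` with
#'   `genes`, `exons`, `splice_sites`, `sf_sites` and `motif_loci`.
#' @export
make_genome <- function(config, seed) {
  with_seed(seed, {
    gc <- config$gc
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- stats::setNames(vapply(seq_len(config$n_contigs), function(i) {
      paste(sample(names(probs), config$contig_length, TRUE, probs),
            collapse = "")
    }, character(1)), sprintf("ctg%02d", seq_len(config$n_contigs)))

    # gene layout: fixed gap, alternating strands, 3 exons per gene
    gap <- 200L
    ng <- config$genes_per_contig
    glen <- (config$contig_length - (ng + 1L) * gap) %/% ng
    if (glen < 2000L) stop("contig too short for requested gene layout")
    genes <- exons <- splice <- list()
    gid <- 0L
    for (ctg in names(seqs)) {
      for (j in seq_len(ng)) {
        gid <- gid + 1L
        gstart <- gap + (j - 1L) * (glen + gap)
        strand <- if (gid %% 2L == 1L) "+" else "-"
        # two introns at jittered thirds; exon/intron sizes stay generous
        b1 <- round(glen * stats::runif(1, 0.25, 0.40))
        b2 <- round(glen * stats::runif(1, 0.60, 0.75))
        ilen <- round(glen * 0.05)
        ex <- rbind(c(0L, b1), c(b1 + ilen, b2), c(b2 + ilen, glen))
        genes[[gid]] <- data.frame(gene_id = gid, contig = ctg,
                                   strand = strand, start = gstart,
                                   end = gstart + glen)
        exons[[gid]] <- data.frame(gene_id = gid, contig = ctg,
                                   strand = strand,
                                   start = gstart + ex[, 1],
                                   end = gstart + ex[, 2])
        # internal edges: last base of upstream exon, first of downstream
        sp <- c(gstart + ex[1:2, 2] - 1L, gstart + ex[2:3, 1])
        splice[[gid]] <- data.frame(contig = ctg, pos = sort(sp),
                                    strand = strand)
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    splice <- do.call(rbind, splice)

    # motif loci on a jittered grid in transcript coordinates
    n_loci <- config$n_m6a + config$n_footprints
    cand <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      L <- g$end - g$start
      grid <- seq(30L, L - 31L, by = config$site_spacing)
      t <- grid + sample(seq(-20L, 20L), length(grid), TRUE)
      cand[[i]] <- data.frame(gene_id = g$gene_id, t = t)
    }
    cand <- do.call(rbind, cand)
    if (nrow(cand) < n_loci)
      stop("contigs too short to host ", n_loci, " motif loci")

    # slack loci cover later drops around the forced splice-edge motif
    loci <- cand[sample(nrow(cand), min(nrow(cand), n_loci + 8L)), ]
    if (isTRUE(config$m6a_at_splice_edge)) {
      # force locus 1's adenosine onto gene 1's first donor edge
      g1 <- genes[1, ]
      donor <- min(splice$pos[splice$contig == g1$contig &
                              splice$strand == g1$strand])
      t_edge <- genomic_to_tx(g1, donor)
      near <- loci$gene_id == 1L & abs(loci$t - t_edge) < 60L
      loci <- loci[!near, , drop = FALSE]
      loci <- rbind(data.frame(gene_id = 1L, t = t_edge), loci)
    }
    loci <- loci[seq_len(min(nrow(loci), n_loci)), , drop = FALSE]
    if (nrow(loci) < n_loci)
      stop("contigs too short to host ", n_loci, " motif loci")

    # write RGACT (an RGAC instance, GGACU-like) into the sequence
    loci$r_base <- sample(c("A", "G"), nrow(loci), TRUE)
    if (isTRUE(config$m6a_at_splice_edge)) loci$r_base[1] <- "G"
    loci$contig <- genes$contig[loci$gene_id]
    loci$strand <- genes$strand[loci$gene_id]
    loci$pos_a <- rep(NA_integer_, nrow(loci))
    for (i in seq_len(nrow(loci))) {
      g <- genes[loci$gene_id[i], ]
      motif <- paste0(loci$r_base[i], "GACT")
      gA <- tx_to_genomic(g, loci$t[i])
      if (g$strand == "+") {
        substr(seqs[[g$contig]], gA - 1L, gA + 3L) <- motif
      } else {
        substr(seqs[[g$contig]], gA - 1L, gA + 3L) <- revcomp(motif)
      }
      loci$pos_a[i] <- gA
    }
    rownames(loci) <- NULL

    # splicing-factor anchors: a fraction sit near motif loci (the reader
    # concentrates around splice-regulatory regions), the rest are uniform
    n_sf <- config$n_sf_sites
    n_near <- round(config$sf_near_fraction * n_sf)
    sf <- list()
    if (n_near > 0) {
      pick <- sample(nrow(loci), n_near, replace = n_near > nrow(loci))
      sf[[1]] <- data.frame(contig = loci$contig[pick],
                            pos = loci$pos_a[pick] +
                              sample(seq(-10L, 10L), n_near, TRUE),
                            strand = loci$strand[pick])
    }
    if (n_sf - n_near > 0) {
      pick <- sample(nrow(genes), n_sf - n_near, TRUE)
      g <- genes[pick, ]
      sf[[2]] <- data.frame(
        contig = g$contig,
        pos = g$start + 30L +
          floor(stats::runif(nrow(g)) * (g$end - g$start - 60L)),
        strand = g$strand)
    }
    sf <- if (length(sf)) do.call(rbind, sf) else
      data.frame(contig = character(0), pos = integer(0),
                 strand = character(0))
    rownames(sf) <- NULL

    model <- structure(list(genes = genes, exons = exons,
                            splice_sites = splice, sf_sites = sf,
                            motif_loci = loci),
                       class = "gene_model")
    list(genome = genome_ref(seqs), model = model)
  })
}

#' Plant ground truth: m6A residues, reader footprints, SNP confounders
#'
#' m6A residues occupy the adenosine of the first `n_m6a` planted RGAC
#' loci. A fraction `overlap_fraction` of footprint anchors is placed
#' within 5 nt of a (distinct) m6A; the remainder sit at unused motif loci,
#' which the generator spaces >= 50 nt from every m6A. SNPs are planted at
#' transcript-sense C positions directly 3' of an adenosine (the exact
#' context a cross-link-induced C>T would mimic), away from planted loci.
#'
#' @param genome,model output of [make_genome()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A `sim_truth` list: `m6a`, `anchors`, `snps` (all genomic,
#'   0-based), plus the `model` and `config` used.
#' @export
plant_truth <- function(genome, model, config, seed) {
  with_seed(seed, {
    loci <- model$motif_loci
    if (nrow(loci) < config$n_m6a + config$n_footprints)
      stop("not enough motif loci for requested truth")
    m6a_loci <- loci[seq_len(config$n_m6a), , drop = FALSE]
    m6a <- data.frame(contig = m6a_loci$contig, pos = m6a_loci$pos_a,
                      strand = m6a_loci$strand, gene_id = m6a_loci$gene_id,
                      t = m6a_loci$t)
    stopifnot(all(mapply(function(c, p, s)
      genome_base(genome, c, p) == (if (s == "+") "A" else "T"),
      m6a$contig, m6a$pos, m6a$strand)))

    n_ov <- round(config$overlap_fraction * config$n_footprints)
    n_far <- config$n_footprints - n_ov
    if (n_ov > nrow(m6a) && config$n_footprints > 0)
      stop("overlap_fraction infeasible: more overlapping anchors than m6A")
    anchors <- list()
    if (n_ov > 0) {
      pick <- sample(nrow(m6a), n_ov)
      off <- sample(seq(-5L, 5L), n_ov, TRUE)
      g <- model$genes[m6a$gene_id[pick], ]
      tt <- m6a$t[pick] + off
      anchors[[1]] <- data.frame(
        contig = m6a$contig[pick],
        pos = ifelse(g$strand == "+", g$start + tt, g$end - 1L - tt),
        strand = m6a$strand[pick], gene_id = m6a$gene_id[pick], t = tt)
    }
    if (n_far > 0) {
      far <- loci[config$n_m6a + seq_len(n_far), , drop = FALSE]
      # anchor at the motif's A+1 (the C), transcript sense
      g <- model$genes[far$gene_id, ]
      tt <- far$t + 1L
      anchors[[2]] <- data.frame(
        contig = far$contig,
        pos = ifelse(g$strand == "+", g$start + tt, g$end - 1L - tt),
        strand = far$strand, gene_id = far$gene_id, t = tt)
    }
    anchors <- if (length(anchors)) do.call(rbind, anchors) else
      data.frame(contig = character(0), pos = integer(0),
                 strand = character(0), gene_id = integer(0), t = integer(0))
    rownames(anchors) <- NULL

    snps <- plant_snps(genome, model, config)
    structure(list(m6a = m6a, anchors = anchors, snps = snps,
                   model = model, config = config),
              class = "sim_truth")
  })
}

plant_snps <- function(genome, model, config) {
  if (config$n_snp == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), t = integer(0),
                      gene_id = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0)))
  cand <- list()
  for (i in seq_len(nrow(model$genes))) {
    g <- model$genes[i, ]
    tx <- tx_seq(genome, g)
    # C of an AC dinucleotide: mimics C>T at +1 of an adenosine
    hits <- gregexpr("AC", tx, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    t_c <- as.integer(hits)              # 0-based position of the C
    loci_t <- model$motif_loci$t[model$motif_loci$gene_id == g$gene_id]
    ok <- t_c > 30L & t_c < (g$end - g$start - 30L)
    if (length(loci_t))
      ok <- ok & vapply(t_c, function(t) all(abs(t - loci_t) > 30L), logical(1))
    if (any(ok))
      cand[[length(cand) + 1L]] <- data.frame(gene_id = g$gene_id, t = t_c[ok])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) < config$n_snp)
    stop("not enough AC contexts to plant ", config$n_snp, " SNPs")
  pick <- cand[sample(nrow(cand), config$n_snp), ]
  g <- model$genes[pick$gene_id, ]
  data.frame(
    contig = g$contig,
    pos = ifelse(g$strand == "+", g$start + pick$t, g$end - 1L - pick$t),
    strand = g$strand, t = pick$t, gene_id = pick$gene_id,
    ref = ifelse(g$strand == "+", "C", "G"),   # genomic sense
    alt = ifelse(g$strand == "+", "T", "A"),
    af = config$snp_af)
}

#' Simulate iCLIP/miCLIP reads with cross-link signatures
#'
#' Reads are sampled uniformly over gene bodies at the configured unique
#' depth, plus an immunoprecipitation-enrichment component: each planted
#' site draws `(site_enrichment - 1) x depth` additional reads that cross
#' it, so coverage peaks at cross-link sites as in a real CLIP library.
#' A read crossing a planted site is cross-linked at the site's
#' signature position (m6A: the +1 base; footprint: the anchor itself) and
#' independently (a) carries the cross-link substitution there with
#' probability `p_mut` (C>T at m6A + 1; a transition at footprint anchors)
#' and (b) is truncated so its 5' end is cross-link + 1 with probability
#' `p_trunc` (a truncated read therefore cannot also show the
#' substitution, which lies 5' of its new start). SNP alleles are emitted
#' at their allele fraction in all overlapping reads; background
#' substitutions are uniform over read bases. PCR duplicates (exact
#' copies) are appended at rate `pcr_rate`.
#'
#' Sequence strings are not materialised here; [simulate_clip()] builds
#' them for FASTQ/SAM output, while [sim_alignments()] converts the event
#' stream directly into alignments for fast in-memory analysis.
#'
#' @param genome a [genome_ref()].
#' @param truth a `sim_truth` from [plant_truth()].
#' @param seed integer seed.
#' @return A `clip_sim` object: `reads`, `mm` (genomic-sense mismatch
#'   events), `events` (per-read cross-link labels), `truth`.
#' @export
sim_clip_reads <- function(genome, truth, seed) {
  config <- truth$config
  with_seed(seed, {
    all_reads <- list(); all_mm <- list(); all_ev <- list()
    for (sample in names(config$sample_sites)) {
      sites <- if (config$sample_sites[[sample]] == "m6a") truth$m6a else
        truth$anchors
      xl_shift <- if (config$sample_sites[[sample]] == "m6a") 1L else 0L
      for (i in seq_len(nrow(truth$model$genes))) {
        g <- truth$model$genes[i, ]
        part <- sim_gene_reads(genome, truth, config, g, sample,
                               sites[sites$gene_id == g$gene_id, , drop = FALSE],
                               xl_shift)
        all_reads[[length(all_reads) + 1L]] <- part$reads
        all_mm[[length(all_mm) + 1L]] <- part$mm
        all_ev[[length(all_ev) + 1L]] <- part$events
      }
    }
    reads <- do.call(rbind, all_reads)
    rownames(reads) <- NULL
    # re-key mismatch rows to global read indices
    off <- cumsum(c(0L, vapply(all_reads, nrow, integer(1))))
    mm <- do.call(rbind, mapply(function(m, o) {
      if (nrow(m)) m$aln <- m$aln + o
      m
    }, all_mm, off[-length(off)], SIMPLIFY = FALSE))
    events <- do.call(rbind, all_ev)
    rownames(events) <- NULL

    reads$dup_of <- NA_character_
    n_dup <- round(config$pcr_rate * nrow(reads))
    if (n_dup > 0) {
      src <- sample(nrow(reads), n_dup, TRUE)
      dup <- reads[src, , drop = FALSE]
      dup$dup_of <- reads$read_id[src]
      dup$read_id <- sprintf("%s_dup%06d", dup$read_id,
                             seq_len(n_dup))
      if (nrow(mm)) {
        grp <- split(seq_len(nrow(mm)), mm$aln)
        hit <- match(as.character(src), names(grp))
        pieces <- lapply(which(!is.na(hit)), function(j) {
          d <- mm[grp[[hit[j]]], , drop = FALSE]
          d$aln <- nrow(reads) + j
          d
        })
        if (length(pieces)) mm <- rbind(mm, do.call(rbind, pieces))
      }
      reads <- rbind(reads, dup)
      rownames(reads) <- NULL
    }
    structure(list(reads = reads, mm = mm, events = events, truth = truth),
              class = "clip_sim")
  })
}

# one gene x one sample; works in transcript coordinates, converts at end
sim_gene_reads <- function(genome, truth, config, g, sample, sites, xl_shift) {
  L <- g$end - g$start
  mean_len <- mean(config$read_len)
  n <- max(0L, round(config$depth * L / mean_len))
  if (n == 0L) stop("zero-coverage configuration for gene ", g$gene_id)
  len <- sample(seq(config$read_len[1], config$read_len[2]), n, TRUE)
  s <- floor(stats::runif(n) * (L - len + 1))

  xl <- sort(sites$t + xl_shift)
  # immunoprecipitation enriches fragments crossing a cross-link site:
  # add (enrichment - 1) x depth extra reads over each site
  if (length(xl) && config$site_enrichment > 1) {
    lam <- (config$site_enrichment - 1) * config$depth
    n_x <- stats::rpois(length(xl), lam)
    if (sum(n_x) > 0) {
      xs <- rep(xl, n_x)
      xlen <- sample(seq(config$read_len[1], config$read_len[2]),
                     length(xs), TRUE)
      xstart <- pmax(0L, pmin(L - xlen,
                              xs - floor(stats::runif(length(xs)) * xlen)))
      s <- c(s, xstart)
      len <- c(len, xlen)
      n <- length(s)
    }
  }
  site_of <- rep(NA_integer_, n)
  if (length(xl)) {
    j <- findInterval(s - 0.5, xl) + 1L
    cov <- j <= length(xl) & xl[pmin(j, length(xl))] <= s + len - 1L
    site_of[cov] <- j[cov]
  }
  covered <- !is.na(site_of)
  trunc <- covered & stats::runif(n) < config$p_trunc
  s2 <- s; len2 <- len
  s2[trunc] <- xl[site_of[trunc]] + 1L
  len2[trunc] <- s[trunc] + len[trunc] - s2[trunc]
  keep <- len2 >= 1L
  mut <- covered & !trunc & stats::runif(n) < config$p_mut

  tx <- tx_seq(genome, g)
  ev <- list()
  if (any(mut & keep)) {
    w <- which(mut & keep)
    t_pos <- xl[site_of[w]]
    ref <- substring(tx, t_pos + 1L, t_pos + 1L)
    ev[[1]] <- data.frame(read = w, t = t_pos, ref = ref,
                          alt = chartr("ACGT", "GTAC", ref))  # transitions
  }
  snps <- truth$snps[truth$snps$gene_id == g$gene_id, , drop = FALSE]
  if (nrow(snps)) {
    for (k in seq_len(nrow(snps))) {
      tpos <- snps$t[k]
      w <- which(keep & s2 <= tpos & tpos <= s2 + len2 - 1L &
                   stats::runif(n) < snps$af[k])
      if (length(w))
        ev[[length(ev) + 1L]] <- data.frame(
          read = w, t = tpos,
          ref = substring(tx, tpos + 1L, tpos + 1L), alt = "T")
    }
  }
  if (config$bg_rate > 0) {
    tot <- sum(len2[keep])
    n_err <- stats::rbinom(1L, tot, config$bg_rate)
    if (n_err > 0) {
      kept <- which(keep)
      cum <- cumsum(len2[kept])
      b <- sample.int(tot, n_err)
      r <- kept[findInterval(b - 1L, c(0L, cum))]
      o <- b - 1L - c(0L, cum)[findInterval(b - 1L, c(0L, cum))]
      tpos <- s2[r] + o
      ref <- substring(tx, tpos + 1L, tpos + 1L)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1), USE.NAMES = FALSE)
      ev[[length(ev) + 1L]] <- data.frame(read = r, t = tpos, ref = ref,
                                          alt = alt)
    }
  }
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(read = integer(0), t = integer(0),
               ref = character(0), alt = character(0))
  ev <- ev[!duplicated(ev[c("read", "t")]), , drop = FALSE]  # planted first

  idx <- which(keep)
  read_id <- sprintf("%s_g%d_%06d", sample, g$gene_id, idx)
  # genomic placement
  if (g$strand == "+") {
    start_g <- g$start + s2[idx]
  } else {
    start_g <- g$end - (s2[idx] + len2[idx])
  }
  reads <- data.frame(read_id = read_id, sample = sample, contig = g$contig,
                      strand = g$strand, start = start_g, span = len2[idx],
                      gene_id = g$gene_id, tstart = s2[idx],
                      stringsAsFactors = FALSE)
  ev <- ev[ev$read %in% idx, , drop = FALSE]
  mm <- if (nrow(ev)) {
    aln <- match(ev$read, idx)
    gpos <- if (g$strand == "+") g$start + ev$t else g$end - 1L - ev$t
    data.frame(aln = aln,
               offset = gpos - start_g[aln],
               ref = if (g$strand == "+") ev$ref else comp_base(ev$ref),
               alt = if (g$strand == "+") ev$alt else comp_base(ev$alt),
               stringsAsFactors = FALSE)
  } else empty_mm()
  events <- data.frame(read_id = read_id, sample = sample,
                       site = site_of[idx],
                       mutated = mut[idx], truncated = trunc[idx],
                       stringsAsFactors = FALSE)
  list(reads = reads, mm = mm, events = events)
}

#' Convert a simulation to in-memory alignments for one sample
#'
#' @param sim a `clip_sim` from [sim_clip_reads()].
#' @param sample sample name (default: first configured).
#' @param unique_only drop PCR duplicate copies (truth-level dedup).
#' @return A [clip_alignments()] object.
#' @export
sim_alignments <- function(sim, sample = NULL, unique_only = TRUE) {
  if (is.null(sample)) sample <- sim$reads$sample[1]
  keep <- which(sim$reads$sample == sample &
                  (!unique_only | is.na(sim$reads$dup_of)))
  reads <- sim$reads[keep, c("read_id", "contig", "strand", "start", "span")]
  reads$is_unique <- TRUE
  rownames(reads) <- NULL
  mm <- sim$mm[sim$mm$aln %in% keep, , drop = FALSE]
  mm$aln <- match(mm$aln, keep)
  rownames(mm) <- NULL
  clip_alignments(reads, mm)
}

# transcript-sense sequence strings for all reads (barcode-free)
sim_read_seqs <- function(sim, genome) {
  r <- sim$reads
  seqs <- character(nrow(r))
  for (ctg in unique(r$contig)) {
    w <- which(r$contig == ctg)
    seqs[w] <- substring(genome$seq[[ctg]], r$start[w] + 1L,
                         r$start[w] + r$span[w])
  }
  if (nrow(sim$mm)) {
    for (j in seq_len(nrow(sim$mm))) {
      i <- sim$mm$aln[j]; o <- sim$mm$offset[j]
      substr(seqs[i], o + 1L, o + 1L) <- sim$mm$alt[j]
    }
  }
  neg <- r$strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  seqs
}

#' Simulate a CLIP experiment and write FASTQ, truth SAM and truth BEDs
#'
#' Thin file-emitting wrapper over [sim_clip_reads()]: the FASTQ carries
#' per-sample barcode prefixes and PCR duplicates; the SAM holds truth
#' alignments for every emitted read; truth BEDs give planted m6A
#' positions, footprint anchors and SNPs (plus a minimal SNP VCF for the
#' masking path).
#'
#' @param genome a [genome_ref()].
#' @param truth a `sim_truth` from [plant_truth()].
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the `clip_sim` object and output paths.
#' @export
simulate_clip <- function(genome, truth, seed, dir) {
  config <- truth$config
  sim <- sim_clip_reads(genome, truth, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- sim_read_seqs(sim, genome)

  fq <- file.path(dir, "reads.fastq")
  bc <- config$barcodes[sim$reads$sample]
  full <- paste0(bc, seqs)
  writeLines(as.vector(rbind(paste0("@", sim$reads$read_id), full,
                             "+", strrep("I", nchar(full)))), fq)

  sam <- file.path(dir, "truth.sam")
  aln <- clip_alignments(
    data.frame(read_id = sim$reads$read_id, contig = sim$reads$contig,
               strand = sim$reads$strand, start = sim$reads$start,
               span = sim$reads$span, is_unique = is.na(sim$reads$dup_of),
               stringsAsFactors = FALSE),
    sim$mm)
  write_alignments(aln, genome, sam)

  beds <- list(
    m6a = file.path(dir, "truth_m6a.bed"),
    anchors = file.path(dir, "truth_anchors.bed"),
    snps = file.path(dir, "truth_snps.bed"))
  write_sites_bed(truth$m6a[c("contig", "pos", "strand")], beds$m6a, genome)
  write_sites_bed(truth$anchors[c("contig", "pos", "strand")], beds$anchors,
                  genome)
  write_sites_bed(truth$snps[c("contig", "pos", "strand")], beds$snps, genome)
  vcf <- file.path(dir, "truth_snps.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\tsnp%d\t%s\t%s\t.\t.\tAF=%g",
                       truth$snps$contig, truth$snps$pos + 1L,
                       seq_len(nrow(truth$snps)), truth$snps$ref,
                       truth$snps$alt, truth$snps$af)), vcf)
  fa <- file.path(dir, "genome.fa")
  write_fasta(genome, fa)
  invisible(list(sim = sim, fastq = fq, sam = sam, beds = beds, vcf = vcf,
                 fasta = fa))
}
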