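# shared fixtures and independent oracles, all built in code

# deterministic random genome without gene structure
toy_genome <- function(len = 200L, seed = 1L, name = "c1") {
  set.seed(seed)
  genome_ref(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), name))
}

# hand-build an alignment set from (start, span, strand) plus planted
# mismatches given in genomic sense: list of c(aln, offset, alt)
manual_alignments <- function(genome, start, span,
                              strand = rep("+", length(start)),
                              contig = rep(names(genome$seq)[1], length(start)),
                              mismatches = list()) {
  reads <- data.frame(
    read_id = sprintf("r%03d", seq_along(start)), contig = contig,
    strand = strand, start = as.integer(start), span = as.integer(span),
    is_unique = TRUE, stringsAsFactors = FALSE)
  mm <- if (length(mismatches)) {
    do.call(rbind, lapply(mismatches, function(x) {
      i <- x[[1]]; o <- as.integer(x[[2]])
      data.frame(aln = i, offset = o,
                 ref = genome_base(genome, reads$contig[i],
                                   reads$start[i] + o),
                 alt = x[[3]], stringsAsFactors = FALSE)
    }))
  } else clipnucleo:::empty_mm()
  clip_alignments(reads, mm)
}

# brute-force recount of k, m, t — the independent tally oracle
brute_force_tally <- function(aln, genome) {
  r <- aln$reads
  k <- list(); t <- list()
  for (ctg in names(genome$seq)) {
    len <- genome$len[[ctg]]
    for (strand in c("+", "-")) {
      kv <- integer(len); tv <- integer(len)
      for (i in which(r$contig == ctg & r$strand == strand)) {
        for (p in seq(r$start[i], r$start[i] + r$span[i] - 1L))
          kv[p + 1L] <- kv[p + 1L] + 1L
        xl <- if (strand == "+") r$start[i] - 1L else r$start[i] + r$span[i]
        if (xl >= 0L && xl < len) tv[xl + 1L] <- tv[xl + 1L] + 1L
      }
      k[[ctg]][[strand]] <- kv
      t[[ctg]][[strand]] <- tv
    }
  }
  m <- list()
  if (nrow(aln$mm)) {
    for (j in seq_len(nrow(aln$mm))) {
      i <- aln$mm$aln[j]
      pos <- r$start[i] + aln$mm$offset[j]
      neg <- r$strand[i] == "-"
      ref <- if (neg) chartr("ACGT", "TGCA", aln$mm$ref[j]) else aln$mm$ref[j]
      alt <- if (neg) chartr("ACGT", "TGCA", aln$mm$alt[j]) else aln$mm$alt[j]
      key <- paste(r$contig[i], r$strand[i], pos, ref, alt)
      m[[key]] <- (if (is.null(m[[key]])) 0L else m[[key]]) + 1L
    }
  }
  list(k = k, t = t, m = m)
}

# small planted-truth simulation shared by several tests
small_sim_cfg <- function(...) {
  sim_config(n_contigs = 1L, contig_length = 20000L, n_m6a = 30L,
             n_footprints = 30L, n_snp = 5L, n_sf_sites = 20L,
             depth = 15, ...)
}

# a single-gene truth object built by hand (for strand-symmetry checks)
manual_truth <- function(genome, strand, m6a_t, cfg) {
  len <- genome$len[[1]]
  genes <- data.frame(gene_id = 1L, contig = names(genome$seq)[1],
                      strand = strand, start = 0L, end = len)
  pos <- if (strand == "+") m6a_t else len - 1L - m6a_t
  structure(list(
    m6a = data.frame(contig = genes$contig, pos = pos, strand = strand,
                     gene_id = 1L, t = m6a_t),
    anchors = data.frame(contig = character(0), pos = integer(0),
                         strand = character(0), gene_id = integer(0),
                         t = integer(0)),
    snps = data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), t = integer(0),
                      gene_id = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0)),
    model = list(genes = genes),
    config = cfg), class = "sim_truth")
}

# Kolmogorov-Smirnov distance to Uniform(0,1)
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(p - (seq_len(n) - 1) / n), abs(p - seq_len(n) / n))
}

# exact rank-sum p by full enumeration of group assignments
enumerate_ranksum_p <- function(x, y, alternative = "less") {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(n, nx)
  sums <- colSums(matrix(r[idx], nrow = nx))
  switch(alternative,
         less = mean(sums <= obs),
         greater = mean(sums >= obs),
         two.sided = min(1, 2 * min(mean(sums <= obs), mean(sums >= obs))))
}
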