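test_that("tally matches an independent brute-force recount", {
  set.seed(51)
  for (rep in 1:5) {
    g <- toy_genome(80L, seed = 50L + rep)
    n <- sample(10:50, 1)
    span <- sample(5:15, n, TRUE)
    start <- sapply(span, function(s) sample(0:(80 - s), 1))
    strand <- sample(c("+", "-"), n, TRUE)
    mism <- list()
    for (i in sample(n, 8)) {
      o <- sample(0:(span[i] - 1L), 1)
      ref <- genome_base(g, "c1", start[i] + o)
      mism[[length(mism) + 1L]] <-
        list(i, o, sample(setdiff(c("A", "C", "G", "T"), ref), 1))
    }
    aln <- manual_alignments(g, start, span, strand, mismatches = mism)
    tl <- suppressWarnings(tally_alignments(aln, g))
    bf <- brute_force_tally(aln, g)
    expect_identical(tl$k[["c1"]], bf$k[["c1"]])
    expect_identical(tl$t[["c1"]], bf$t[["c1"]])
    got <- stats::setNames(tl$m$m, paste(tl$m$contig, tl$m$strand, tl$m$pos,
                                         tl$m$ref, tl$m$alt))
    expect_mapequal(as.list(got), bf$m)
  }
})

test_that("cross-link position is read start - 1 on the transcript strand", {
  g <- toy_genome(200L, seed = 52L)
  aln <- manual_alignments(g, start = c(100L, 100L), span = c(10L, 10L),
                           strand = c("+", "-"))
  tl <- tally_alignments(aln, g)
  expect_equal(tl$t[["c1"]][["+"]][99L + 1L], 1L)   # plus: start - 1
  expect_equal(tl$t[["c1"]][["-"]][110L + 1L], 1L)  # minus: 5' end + 1
})

test_that("tally rejects non-unique input and wrong reference bases", {
  g <- toy_genome(40L, seed = 53L)
  aln <- manual_alignments(g, 5L, 10L)
  aln$reads$is_unique <- FALSE
  expect_error(tally_alignments(aln, g), "deduplicated")
  ref <- genome_base(g, "c1", 7L)
  bad <- manual_alignments(g, 5L, 10L,
                           mismatches = list(list(1L, 2L, "A")))
  bad$mm$ref <- setdiff(c("A", "C", "G"), ref)[1]   # corrupt the record
  expect_error(tally_alignments(bad, g), "data-integrity")
})

test_that("a saturated mutation site has permutation FDR zero", {
  g <- toy_genome(100L, seed = 54L)
  # 20 identical-span reads, all carrying C>T at the same position
  ref <- genome_base(g, "c1", 30L)
  aln <- manual_alignments(
    g, start = rep(20L, 20L), span = rep(20L, 20L),
    mismatches = lapply(1:20, function(i) list(i, 10L, "T")))
  aln$mm$ref <- ref; aln$mm$alt <- "T"
  g$seq[["c1"]] <- paste0(substr(g$seq[["c1"]], 1, 30), "C",
                          substr(g$seq[["c1"]], 32, 100))   # force ref C
  aln$mm$ref <- "C"
  tl <- tally_alignments(aln, g)
  cims <- call_cims(tl, "C>T", n_perm = 20L, seed = 55L)
  expect_equal(nrow(cims), 1L)
  expect_equal(cims$k, 20L)
  expect_equal(cims$m, 20L)
  expect_equal(cims$fdr, 0)
})

test_that("permutation FDR is non-increasing in m within a coverage stratum", {
  cfg <- small_sim_cfg(depth = 20, bg_rate = 0.002, n_snp = 0L)
  gm <- make_genome(cfg, 56L)
  tr <- plant_truth(gm$genome, gm$model, cfg, 57L)
  sim <- sim_clip_reads(gm$genome, tr, 58L)
  tl <- tally_alignments(sim_alignments(sim), gm$genome)
  cims <- call_cims(tl, "C>T", n_perm = 10L, seed = 59L)
  expect_true(all(cims$m >= 1L))
  expect_true(all(cims$ratio > 0 & cims$ratio <= 1))
  for (k in unique(cims$k)) {
    s <- cims[cims$k == k, ]
    s <- s[order(s$m), ]
    expect_true(all(diff(s$fdr) <= 1e-12))
  }
})

test_that("CITS binomial p matches the exact tail and BH ordering holds", {
  # white-box cluster: 10 covered positions, 10 truncations, 5 at one site
  g <- genome_ref(c(c1 = strrep("ACGT", 10)))
  len <- 40L
  mk <- function(v) { x <- integer(len); x[v + 1L] <- 1L; x }
  kvec <- integer(len); kvec[(10:19) + 1L] <- 2L
  tvec <- integer(len)
  tvec[15L + 1L] <- 5L
  tvec[c(11L, 12L, 13L, 17L, 18L) + 1L] <- 1L
  tl <- structure(list(
    k = list(c1 = list("+" = kvec, "-" = integer(len))),
    t = list(c1 = list("+" = tvec, "-" = integer(len))),
    m = data.frame(), mm_events = data.frame(), lib_size = 10L),
    class = "site_tally")
  cits <- call_cits(tl)
  expect_equal(unique(cits$L), 10L)
  expect_equal(unique(cits$n), 10L)
  hot <- cits[cits$pos == 15L, ]
  expect_equal(hot$p, sum(dbinom(5:10, 10, 1 / 10)))  # exact tail oracle
  expect_equal(cits$q, bh_adjust(cits$p))
  expect_true(all(cits$q >= cits$p))

  # degenerate single-position cluster: p = 1
  k1 <- integer(len); k1[5L + 1L] <- 3L
  t1 <- integer(len); t1[5L + 1L] <- 4L
  tl1 <- structure(list(
    k = list(c1 = list("+" = k1, "-" = integer(len))),
    t = list(c1 = list("+" = t1, "-" = integer(len))),
    m = data.frame(), mm_events = data.frame(), lib_size = 4L),
    class = "site_tally")
  c1 <- call_cits(tl1)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$p, 1)
})

test_that("CITS from alignments finds a planted truncation hotspot", {
  g <- toy_genome(400L, seed = 60L)
  # background: uniform read starts; hotspot: many reads starting at 201
  set.seed(61)
  bg_start <- sample(50:330, 120, TRUE)
  starts <- c(bg_start, rep(201L, 15L))
  aln <- manual_alignments(g, starts, rep(20L, length(starts)))
  tl <- tally_alignments(aln, g)
  cits <- call_cits(tl)
  top <- cits[which.min(cits$p), ]
  expect_equal(top$pos, 200L)
  expect_lt(top$q, 0.05)
})

test_that("BH adjustment matches closed-form cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("site calls are strand-symmetric in transcript coordinates", {
  len <- 6000L
  set.seed(62)
  fwd <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  m6a_t <- c(1000L, 2500L, 4200L)
  # write GGACT at each site in transcript sense of the respective strand
  for (t in m6a_t) substr(fwd, t - 1L, t + 3L) <- "GGACT"
  g_fwd <- genome_ref(c(c1 = fwd))
  g_rev <- genome_ref(c(c1 = revcomp(fwd)))
  cfg <- sim_config(p_mut = 0.4, p_trunc = 0.2, bg_rate = 0, n_snp = 0L,
                    depth = 25, pcr_rate = 0,
                    barcodes = c(miCLIP = "ACGTG"),
                    sample_sites = c(miCLIP = "m6a"))
  res <- lapply(c("+", "-"), function(strand) {
    g <- if (strand == "+") g_fwd else g_rev
    tr <- manual_truth(g, strand, m6a_t, cfg)
    sim <- sim_clip_reads(g, tr, 63L)
    tl <- tally_alignments(sim_alignments(sim), g)
    cims <- call_cims(tl, "C>T", 10L, 64L)
    cits <- call_cits(tl)
    m6a <- combine_m6a_calls(call_m6a_from_cims(cims, g, 0.5, 0.1),
                             call_m6a_from_cits(cits, g))
    # back to transcript coordinates
    sort(ifelse(m6a$strand == "+", m6a$pos, len - 1L - m6a$pos))
  })
  expect_identical(res[[1]], res[[2]])
  expect_true(all(m6a_t %in% res[[1]]))
})
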