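sites_df <- function(pos, strand = "+", contig = "c1") {
  n <- length(pos)
  data.frame(contig = rep_len(contig, n), pos = as.integer(pos),
             strand = rep_len(strand, n), stringsAsFactors = FALSE)
}

test_that("site overlap counts and pairing behave as a Venn partition", {
  ov <- overlap_sites(sites_df(100L), sites_df(103L), 5L)
  expect_equal(ov$n_overlap, 1L)
  expect_equal(ov$n_a_only, 0L)

  a <- sites_df(c(10L, 50L, 90L))
  self <- overlap_sites(a, a, 5L)
  expect_equal(self$n_overlap, 3L)
  expect_equal(self$n_a_only + self$n_b_only, 0L)

  # construction oracle: sets >= 50 nt apart never overlap at tol 5
  far <- overlap_sites(sites_df(c(0L, 100L)), sites_df(c(50L, 150L)), 5L)
  expect_equal(far$n_overlap, 0L)

  # strand and contig are respected
  x <- overlap_sites(sites_df(100L, "+"), sites_df(100L, "-"), 5L)
  expect_equal(x$n_overlap, 0L)

  # symmetry and one-to-one pairing on random sets
  set.seed(81)
  for (i in 1:5) {
    a <- sites_df(sample(0:500, 30))
    b <- sites_df(sample(0:500, 40))
    f <- overlap_sites(a, b, 5L)
    r <- overlap_sites(b, a, 5L)
    expect_equal(f$n_overlap, r$n_overlap)
    expect_equal(f$n_a_only + f$n_overlap, nrow(a))
    expect_equal(f$n_b_only + f$n_overlap, nrow(b))
    expect_true(!anyDuplicated(f$pairs$ai) && !anyDuplicated(f$pairs$bi))
  }
})

test_that("metagene profiles are strand-aware and normalized", {
  g <- toy_genome(300L, seed = 82L)
  # one read covering the whole contig: coverage 1 everywhere
  aln <- manual_alignments(g, 0L, 300L)
  tl <- suppressWarnings(tally_alignments(aln, g))
  pr <- metagene_profile(tl, sites_df(150L), halfwidth = 20L)
  expect_equal(pr$intensity, rep(1e6, 41))   # cpm with library size 1

  # asymmetric coverage: minus-strand anchor sees the reversed window
  aln2 <- manual_alignments(g, c(100L, 100L, 140L), c(30L, 30L, 30L),
                            strand = c("-", "-", "-"))
  tl2 <- tally_alignments(aln2, g)
  pr_minus <- metagene_profile(tl2, sites_df(135L, "-"), halfwidth = 20L,
                               normalization = "none")
  kv <- tl2$k[["c1"]][["-"]]
  expect_equal(pr_minus$intensity, rev(kv[(115:155) + 1L]))

  # translation invariance: shift reads and anchors by the same offset
  sh <- 40L
  aln3 <- manual_alignments(g, c(100L, 140L) + sh, c(30L, 30L))
  tl3 <- tally_alignments(aln3, g)
  aln4 <- manual_alignments(g, c(100L, 140L), c(30L, 30L))
  tl4 <- tally_alignments(aln4, g)
  p3 <- metagene_profile(tl3, sites_df(135L + sh), 20L, "none")
  p4 <- metagene_profile(tl4, sites_df(135L), 20L, "none")
  expect_equal(p3$intensity, p4$intensity)

  # edge anchors are dropped with a warning
  expect_warning(metagene_profile(tl4, sites_df(c(5L, 135L)), 20L, "none"),
                 "dropped")
  expect_error(metagene_profile(tl4, sites_df(integer(0))), "no anchors")
})

test_that("planted footprints produce a profile peak at the anchor", {
  cfg <- small_sim_cfg(overlap_fraction = 0, p_trunc = 0.4, depth = 20)
  gm <- make_genome(cfg, 83L)
  tr <- plant_truth(gm$genome, gm$model, cfg, 84L)
  sim <- sim_clip_reads(gm$genome, tr, 85L)
  tl <- tally_alignments(sim_alignments(sim, "NKAP"), gm$genome)
  # IP enrichment concentrates coverage over the cross-link sites
  pr <- suppressWarnings(
    metagene_profile(tl, tr$anchors[c("contig", "pos", "strand")], 50L))
  expect_equal(pr$n_anchors, nrow(tr$anchors))
  peak_at <- pr$offsets[which.max(pr$intensity)]
  expect_lte(abs(peak_at), 5L)
})

test_that("splice proximity grouping is inclusive at the flank boundary", {
  g <- toy_genome(1000L, seed = 86L)
  aln <- manual_alignments(g, c(100L, 500L), c(50L, 50L))
  tl <- tally_alignments(aln, g)
  sp <- sites_df(c(200L, 301L))
  m6a <- sites_df(100L)
  gc <- splice_proximity_test(sp, m6a, tl, flank = 100L)
  expect_equal(gc$sites$near, c(TRUE, FALSE))   # 100 nt in, 201 nt out
  gc2 <- splice_proximity_test(sites_df(c(200L, 201L)), m6a, tl, 100L)
  expect_equal(gc2$sites$near, c(TRUE, FALSE))  # 101 nt is out

  # empty group: NA p with a warning
  expect_warning(
    gc3 <- splice_proximity_test(sites_df(150L), m6a, tl, 100L),
    "empty")
  expect_true(is.na(gc3$p))
})

test_that("IUPAC motif scoring counts R as A or G", {
  expect_equal(motif_score("TTGGACTTTTTTTTTTTTTTT", "RGAC"), 1L)
  expect_equal(motif_score("TTAGACTTTTTTTTTTTTTTT", "RGAC"), 1L)
  expect_equal(motif_score("TTCGACTTTTTTTTTTTTTTT", "RGAC"), 0L)
  expect_equal(motif_score("GGACTTTTTTTTTTTTTGGAC", "RGAC"), 2L)
})

test_that("dinucleotide shuffle preserves composition and endpoints", {
  set.seed(87)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    x <- dinuc_shuffle(s)
    expect_equal(nchar(x), 21L)
    di <- function(z) { ch <- strsplit(z, "")[[1]]
      sort(paste0(ch[-length(ch)], ch[-1])) }
    expect_identical(di(x), di(s))
    expect_identical(substr(x, 1, 1), substr(s, 1, 1))
    expect_identical(substr(x, 21, 21), substr(s, 21, 21))
  }
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r$p, 1 / 20)
  expect_equal(r$p, enumerate_ranksum_p(c(1, 2, 3), c(4, 5, 6), "less"))

  # identical all-tied input: p = 1, not significant
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 5), "two.sided")$p, 1)

  # self-comparison of a varied sample is null
  set.seed(88)
  x <- rnorm(30)
  expect_gt(wilcoxon_rank_sum(x, x, "greater")$p, 0.4)

  # large-sample approximation within 10% of exact enumeration
  for (i in 1:3) {
    x <- rnorm(10); y <- rnorm(10)
    approx_p <- wilcoxon_rank_sum(x, y, "less")$p   # n = 20: normal path
    exact_p <- enumerate_ranksum_p(x, y, "less")
    expect_lt(abs(approx_p - exact_p) / exact_p, 0.10)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty group")
})

test_that("motif enrichment flags planted RGAC footprints, not random ones", {
  cfg <- small_sim_cfg()
  gm <- make_genome(cfg, 89L)
  tr <- plant_truth(gm$genome, gm$model, cfg, 90L)
  # anchors sit on/near planted RGAC loci: strong enrichment
  en <- motif_enrichment(tr$anchors[c("contig", "pos", "strand")],
                         gm$genome, "RGAC", 10L, "shuffle", 91L)
  expect_lt(en$p, 1e-6)
  expect_gt(en$ratio, 1.5)
  # random windows: null
  set.seed(92)
  rnd <- sites_df(sample(100:19000, 30), sample(c("+", "-"), 30, TRUE),
                  names(gm$genome$seq)[1])
  en0 <- motif_enrichment(rnd, gm$genome, "RGAC", 10L, "shuffle", 93L)
  expect_gt(en0$p, 0.05)
})
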