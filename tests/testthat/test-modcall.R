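# genome with known local context: pos 10 = A, pos 11 = C (an AC site on +)
context_genome <- function() {
  s <- strrep("G", 30)
  substr(s, 11, 12) <- "AC"     # 0-based 10 = A, 11 = C
  substr(s, 21, 22) <- "GC"     # 0-based 21 = C with G upstream
  genome_ref(c(c1 = s))
}

cims_row <- function(pos, k, m, fdr = 0, strand = "+", ref = "C",
                     alt = "T") {
  data.frame(contig = "c1", pos = pos, strand = strand, ref = ref,
             alt = alt, k = k, m = m, ratio = m / k, fdr = fdr,
             stringsAsFactors = FALSE)
}

test_that("SNP masking removes exactly the masked positions", {
  sites <- cims_row(c(5L, 11L, 21L), 10L, 2L)
  mask <- data.frame(contig = "c1", start = 11L, end = 12L, strand = "*",
                     label = "snp")
  out <- mask_known_snps(sites, mask)
  expect_equal(out$pos, c(5L, 21L))
  expect_equal(attr(out, "n_masked"), 1L)
  # empty mask is the identity
  id <- mask_known_snps(sites, mask[0, ])
  expect_equal(id$pos, sites$pos)
})

test_that("masking drops fully penetrant SNP candidates but keeps planted m6A", {
  cfg <- small_sim_cfg(snp_af = 1.0, n_snp = 10L, bg_rate = 0, depth = 25,
                       p_trunc = 0,
                       barcodes = c(miCLIP = "ACGTG"),
                       sample_sites = c(miCLIP = "m6a"))
  gm <- make_genome(cfg, 71L)
  tr <- plant_truth(gm$genome, gm$model, cfg, 72L)
  sim <- sim_clip_reads(gm$genome, tr, 73L)
  tl <- tally_alignments(sim_alignments(sim), gm$genome)
  cims <- call_cims(tl, "C>T", 10L, 74L)
  mask <- data.frame(contig = tr$snps$contig, start = tr$snps$pos,
                     end = tr$snps$pos + 1L, strand = "*", label = "snp")
  masked <- mask_known_snps(cims, mask)
  snp_key <- paste(tr$snps$contig, tr$snps$pos)
  # all and only SNP-position candidates removed
  expect_true(all(!paste(masked$contig, masked$pos) %in% snp_key))
  removed <- setdiff(paste(cims$contig, cims$pos),
                     paste(masked$contig, masked$pos))
  expect_setequal(removed, intersect(paste(cims$contig, cims$pos), snp_key))
  # planted m6A +1 candidates are never masked: truth keeps SNPs away
  p1 <- ifelse(tr$m6a$strand == "+", tr$m6a$pos + 1L, tr$m6a$pos - 1L)
  expect_true(all(!paste(tr$m6a$contig, p1) %in% snp_key))
  in_cand <- paste(cims$contig, cims$pos) %in% paste(tr$m6a$contig, p1)
  expect_true(all(paste(cims$contig, cims$pos)[in_cand] %in%
                    paste(masked$contig, masked$pos)))
})

test_that("miCLIP CIMS m6A rule: ratio boundary and adenosine context", {
  g <- context_genome()
  # m/k = 0.50 at the +1 of an A: retained, m6A emitted at the A
  r50 <- call_m6a_from_cims(cims_row(11L, 10L, 5L), g)
  expect_equal(nrow(r50), 1L)
  expect_equal(r50$pos, 10L)
  expect_equal(r50$evidence, "CIMS")
  expect_equal(c(r50$fp_start, r50$fp_end), c(5L, 16L))
  # m/k = 0.60: rejected
  expect_equal(nrow(call_m6a_from_cims(cims_row(11L, 10L, 6L), g)), 0L)
  # upstream base G: rejected even with a good ratio
  expect_equal(nrow(call_m6a_from_cims(cims_row(21L, 10L, 3L), g)), 0L)
  # non-C>T substitution: rejected
  expect_equal(nrow(call_m6a_from_cims(
    cims_row(11L, 10L, 3L, ref = "G", alt = "A"), g)), 0L)
  # optional FDR cut applies on top of the quoted rule
  expect_equal(nrow(call_m6a_from_cims(cims_row(11L, 10L, 5L, fdr = 0.2),
                                       g, fdr = 0.1)), 0L)
})

test_that("minus-strand CIMS m6A places the adenosine at +1 genomic", {
  s <- strrep("G", 30)
  substr(s, 16, 17) <- "GT"  # 0-based 15 = G (tx C on -), 16 = T (tx A)
  g <- genome_ref(c(c1 = s))
  r <- call_m6a_from_cims(cims_row(15L, 10L, 4L, strand = "-"), g)
  expect_equal(r$pos, 16L)
  expect_equal(r$strand, "-")
})

test_that("CITS m6A assignment prefers self, then -1, then +1 adenosines", {
  s <- strrep("G", 40)
  substr(s, 11, 11) <- "A"   # 0-based 10: site is itself A
  substr(s, 21, 22) <- "AC"  # 0-based 21 = C with A at -1
  substr(s, 31, 32) <- "CA"  # 0-based 30 = C with A at +1 only
  g <- genome_ref(c(c1 = s))
  mk <- function(pos, q) data.frame(contig = "c1", pos = pos, strand = "+",
                                    t = 5L, L = 50L, n = 10L, p = q, q = q)
  expect_equal(call_m6a_from_cits(mk(10L, 0.01), g)$pos, 10L)
  expect_equal(call_m6a_from_cits(mk(21L, 0.01), g)$pos, 20L)
  expect_equal(call_m6a_from_cits(mk(30L, 0.01), g)$pos, 31L)
  # no adenosine within one base: rejected
  expect_equal(nrow(call_m6a_from_cits(mk(5L, 0.01), g)), 0L)
  # boundary: q = alpha retained, above alpha rejected
  expect_equal(nrow(call_m6a_from_cits(mk(10L, 0.05), g)), 1L)
  expect_equal(nrow(call_m6a_from_cits(mk(10L, 0.051), g)), 0L)
  # raw-p escape hatch
  d <- mk(10L, 0.2); d$p <- 0.04
  expect_equal(nrow(call_m6a_from_cits(d, g, use_raw_p = TRUE)), 1L)
})

test_that("reader footprints keep the FDR <= 0.1 boundary and carry windows", {
  g <- context_genome()
  cits0 <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), t = integer(0), L = integer(0),
                      n = integer(0), p = numeric(0), q = numeric(0))
  at <- call_reader_footprints(cims_row(100L, 20L, 3L, fdr = 0.10), cits0, g)
  expect_equal(nrow(at), 1L)
  expect_equal(c(at$fp_start, at$fp_end), c(95L, 106L))
  over <- call_reader_footprints(cims_row(100L, 20L, 3L, fdr = 0.11), cits0, g)
  expect_equal(nrow(over), 0L)
  # CIMS branch has no base-context restriction (non-C>T, non-A context)
  any_sub <- call_reader_footprints(
    cims_row(3L, 20L, 3L, fdr = 0.05, ref = "G", alt = "A"), cits0, g)
  expect_equal(nrow(any_sub), 1L)
  expect_equal(any_sub$evidence, "CIMS")
})

test_that("combined m6A calls deduplicate shared positions", {
  g <- context_genome()
  a <- call_m6a_from_cims(cims_row(11L, 10L, 5L), g)
  b <- a; b$evidence <- "CITS"; b$stat <- "q"
  comb <- combine_m6a_calls(a, b)
  expect_equal(nrow(comb), 1L)
  expect_equal(comb$evidence, "CIMS+CITS")
})
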