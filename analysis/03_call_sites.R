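#!/usr/bin/env Rscript
# Stage 3: per-position tallies and single-nucleotide site inference.
# For each sample: unique-tag coverage (k), C>T substitution counts (m)
# and cross-link truncation counts (t); CIMS by within-read permutation
# FDR; CITS by the cluster binomial test with BH correction; known-SNP
# masking; then miCLIP rules -> m6A residues and iCLIP rules -> NKAP
# footprints, each scored against the planted truth.

suppressPackageStartupMessages(library(clipnucleo))
seed <- 20260919L
dir.create("results/sites", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/sites", recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta("scratch/sim/genome.fa")
aln_all <- read_alignments("scratch/sim/truth.sam", genome)
snp_mask <- read_interval_mask("scratch/sim/truth_snps.vcf", genome)

calls <- list(); tallies <- list()
for (s in c("miCLIP", "NKAP")) {
  surv <- read_fastq(file.path("scratch/preprocess", paste0(s, ".fastq")))
  aln <- subset_alignments(aln_all, surv$read_id)
  tl <- tally_alignments(aln, genome)
  tallies[[s]] <- tl
  write_coverage_bedgraph(tl, sprintf("scratch/sites/%s_coverage.bedgraph", s))
  cims <- mask_known_snps(call_cims(tl, "C>T", n_perm = 10L, seed), snp_mask)
  cits <- call_cits(tl)
  write_sites_bed(cims, sprintf("results/sites/%s_cims.bed", s), genome)
  write_sites_bed(cits, sprintf("scratch/sites/%s_cits.bed", s), genome)
  calls[[s]] <- list(cims = cims, cits = cits)
  cat(sprintf("%s: %d unique tags, %d CIMS candidates (%d masked), %d CITS tested\n",
              s, tl$lib_size, nrow(cims), attr(cims, "n_masked"),
              nrow(cits)))
}
saveRDS(tallies, "scratch/tallies.rds")  # bulky; scratch only

m6a <- combine_m6a_calls(
  call_m6a_from_cims(calls$miCLIP$cims, genome, max_ratio = 0.5, fdr = 0.1),
  call_m6a_from_cits(calls$miCLIP$cits, genome, alpha = 0.05))
write_sites_bed(m6a, "results/sites/m6a.bed", genome)

fp <- call_reader_footprints(calls$NKAP$cims, calls$NKAP$cits, genome,
                             fdr = 0.1, alpha = 0.05)
write_sites_bed(fp, "results/sites/footprints.bed", genome)

truth_m6a <- read_sites_bed("scratch/sim/truth_m6a.bed")
truth_fp <- read_sites_bed("scratch/sim/truth_anchors.bed")
sc_m <- score_against_truth(m6a, truth_m6a[c("contig", "pos", "strand")], 0L)
sc_f <- score_against_truth(fp, truth_fp[c("contig", "pos", "strand")], 5L)
tab <- data.frame(
  set = c("m6a", "footprints"),
  n_called = c(sc_m$n_called, sc_f$n_called),
  precision = round(c(sc_m$precision, sc_f$precision), 4),
  recall = round(c(sc_m$recall, sc_f$recall), 4))
write.table(tab, "results/sites/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab)
cat("evidence classes (m6A):\n")
print(table(m6a$evidence))
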