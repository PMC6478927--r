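#!/usr/bin/env Rscript
# Stage 4: integrative footprint analyses.
# (a) m6A / footprint overlap at 5-nt tolerance; (b) metagene intensity of
# reader binding centered at m6A residues and vice versa, plus reader tag
# density around splicing-factor sites; (c) RGAC motif enrichment in 21-nt
# footprint windows vs dinucleotide-shuffled background; (d) reader
# intensity at splice sites near (<= 100 nt) vs not near m6A residues.

suppressPackageStartupMessages(library(clipnucleo))
seed <- 20260919L
dir.create("results/integrate", recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta("scratch/sim/genome.fa")
m6a <- read_sites_bed("results/sites/m6a.bed")
fp <- read_sites_bed("results/sites/footprints.bed")
tallies <- readRDS("scratch/tallies.rds")

ov <- overlap_sites(m6a, fp, tolerance = 5L)
write.table(data.frame(set = c("m6a_only", "overlap", "footprint_only"),
                       n = c(ov$n_a_only, ov$n_overlap, ov$n_b_only)),
            "results/integrate/venn.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(ov)

prof <- list(
  reader_at_m6a = metagene_profile(tallies$NKAP, m6a, 100L),
  m6a_at_footprints = metagene_profile(tallies$miCLIP, fp, 100L),
  reader_at_sf = metagene_profile(tallies$NKAP,
                                  read_sites_bed("scratch/sim/sf_sites.bed"),
                                  100L))
for (nm in names(prof))
  write.table(data.frame(offset = prof[[nm]]$offsets,
                         intensity = prof[[nm]]$intensity),
              sprintf("results/integrate/profile_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
for (nm in names(prof))
  cat(sprintf("profile %-18s peak at offset %+d\n", nm,
              prof[[nm]]$offsets[which.max(prof[[nm]]$intensity)]))

en <- motif_enrichment(fp, genome, "RGAC", n_bg_per_fg = 10L,
                       bg_mode = "shuffle", seed = seed)
write.table(data.frame(motif = en$motif, p = en$p, score_ratio = en$ratio,
                       n_fg = length(en$fg_scores),
                       n_bg = length(en$bg_scores)),
            "results/integrate/motif_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("RGAC enrichment in footprints: p = %.3g, fg/bg score ratio %.2f\n",
            en$p, en$ratio))

splice <- read_sites_bed("scratch/sim/splice_sites.bed")
gc <- splice_proximity_test(splice, m6a, tallies$NKAP, flank = 100L,
                            intensity_window = 10L)
write.table(data.frame(
  group = c("near", "not_near"), n = c(gc$n_near, gc$n_far),
  mean_intensity = c(mean(gc$sites$intensity[gc$sites$near]),
                     mean(gc$sites$intensity[!gc$sites$near])),
  p = gc$p),
  "results/integrate/splice_test.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("splice sites near m6A: %d, not near: %d, rank-sum p = %.3g\n",
            gc$n_near, gc$n_far, gc$p))
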