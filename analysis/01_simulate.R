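#!/usr/bin/env Rscript
# Stage 1: generate the study genome and simulate the two CLIP libraries.
#
# Builds a ~100 kb two-contig toy genome with multi-exon genes, plants 200
# m6A residues on RGAC motifs (one exactly at a splice junction, mirroring
# the pri-miR-25 configuration), 200 reader footprints (70% within 5 nt of
# an m6A), and 20 heterozygous C>T SNP confounders; then simulates a
# miCLIP and an NKAP iCLIP library with cross-link mutations, truncations,
# PCR duplicates and barcodes. Bulky read-level artifacts go to
# scratch/sim/ (regenerated on demand); downstream tables go to results/.

suppressPackageStartupMessages(library(clipnucleo))
seed <- 20260919L

cfg <- sim_config()               # the study conditions
gm <- make_genome(cfg, seed)
truth <- plant_truth(gm$genome, gm$model, cfg, seed + 1L)
out <- simulate_clip(gm$genome, truth, seed + 2L, "scratch/sim")

# stage state the later drivers need: gene model annotation as BED
write_sites_bed(gm$model$splice_sites, "scratch/sim/splice_sites.bed",
                gm$genome)
write_sites_bed(gm$model$sf_sites, "scratch/sim/sf_sites.bed", gm$genome)

cat("genome:", length(gm$genome$seq), "contigs,",
    sum(gm$genome$len), "nt\n")
cat("planted: ", nrow(truth$m6a), "m6A |", nrow(truth$anchors),
    "footprint anchors |", nrow(truth$snps), "SNPs\n")
cat("simulated reads (incl. PCR duplicates):", nrow(out$sim$reads), "\n")
cat("outputs: scratch/sim/{reads.fastq, truth.sam, genome.fa, truth_*.bed}\n")
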