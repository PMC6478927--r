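#!/usr/bin/env Rscript
# Stage 2: demultiplex by experimental barcode, collapse PCR duplicates by
# full-sequence identity, and discard reads shorter than 20 nt.
# Reads scratch/sim/reads.fastq; writes per-sample survivor FASTQs to
# scratch/preprocess/ and the count summary to results/.

suppressPackageStartupMessages(library(clipnucleo))
dir.create("scratch/preprocess", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config()
batch <- read_fastq("scratch/sim/reads.fastq")
pp <- preprocess_reads(batch, cfg$barcodes, min_len = 20L)

for (s in names(pp$samples))
  write_fastq(pp$samples[[s]], file.path("scratch/preprocess",
                                         paste0(s, ".fastq")))
write.table(pp$summary, "results/preprocess_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(pp$summary)
cat("unassigned reads:", pp$n_unassigned, "\n")
dup_rate <- 1 - sum(pp$summary$after_dedup) / sum(pp$summary$demultiplexed)
cat(sprintf("overall duplicate rate: %.1f%%\n", 100 * dup_rate))
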