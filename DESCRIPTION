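Package: clipnucleo
Title: Single-Nucleotide CLIP Analysis: CIMS/CITS Site Calling and m6A
    Footprint Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls single-nucleotide cross-link sites from iCLIP and miCLIP
    sequencing libraries: cross-linking-induced mutation sites (CIMS) by a
    within-read permutation FDR on C>T transition counts, and
    cross-linking-induced truncation sites (CITS) by a binomial test on read
    5'-end pileups with Benjamini-Hochberg correction. Candidate sites are
    filtered into N6-methyladenosine (m6A) residues or RNA-binding-protein
    footprints with known-SNP masking, and integrated by site-set overlap,
    anchored metagene profiles, RGAC motif rank-sum enrichment, and
    splice-site proximity comparisons. A synthetic iCLIP read simulator with
    planted ground truth (methylated adenosines, reader footprints, SNP
    confounders, PCR duplicates, experimental barcodes) makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
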