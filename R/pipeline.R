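#' Score called sites against planted truth
#'
#' One-to-one nearest matching within `tolerance` nt (same contig and
#' strand). Precision = matched / called (NA when nothing was called),
#' recall = matched / truth.
#'
#' @param called,truth site data frames (`contig`, `pos`, `strand`).
#' @param tolerance matching tolerance in nt (default 0: exact position).
#' @return List with `precision`, `recall`, `f1`, `n_called`, `n_truth`,
#'   `n_matched`.
#' @export
score_against_truth <- function(called, truth, tolerance = 0L) {
  if (nrow(called) == 0) {
    return(list(precision = NA_real_, recall = 0, f1 = NA_real_,
                n_called = 0L, n_truth = nrow(truth), n_matched = 0L))
  }
  ov <- overlap_sites(called, truth, tolerance)
  precision <- ov$n_overlap / nrow(called)
  recall <- ov$n_overlap / nrow(truth)
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_called = nrow(called), n_truth = nrow(truth),
       n_matched = ov$n_overlap)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "clipnucleo_run",
    simulate = NULL,                    # sim_config overrides, or NULL
    paths = list(),                     # genome, sam (named), snp_mask,
                                        # splice_sites — file mode
    preprocess = list(min_len = 20L),
    cims = list(sub_type = "C>T", n_perm = 10L),
    cits = list(alpha = 0.05, use_raw_p = FALSE),
    m6a = list(max_ratio = 0.5, fdr = 0.1),
    footprints = list(fdr = 0.1, alpha = 0.05, cits_require_a = TRUE),
    m6a_sample = "miCLIP",
    footprint_sample = "NKAP",
    integrate = list(tolerance = 5L, halfwidth = 100L, flank = 100L,
                     intensity_window = 10L, motif = "RGAC",
                     n_bg_per_fg = 10L, bg_mode = "shuffle")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_pipeline_config <- function(config) {
  if (is.null(config$seed)) stop("config error: a seed is mandatory")
  if (is.null(config$simulate)) {
    for (p in c("genome", "sam")) {
      if (is.null(config$paths[[p]]))
        stop("config error: paths$", p,
             " is required when no simulation block is given")
    }
    for (f in unlist(config$paths)) {
      if (!file.exists(f)) stop("config error: missing input file ", f)
    }
  }
  th <- config$cits$alpha
  if (th < 0 || th > 1) stop("config error: cits alpha outside [0,1]")
  if (config$m6a$max_ratio < 0 || config$m6a$max_ratio > 1)
    stop("config error: m6a max_ratio outside [0,1]")
  invisible(config)
}

#' Run the full CLIP site-calling and integration pipeline
#'
#' Orchestrates simulate (optional) -> preprocess -> tally -> CIMS/CITS ->
#' SNP masking -> m6A / footprint calling -> integrative analyses, writing
#' BED/bedGraph/TSV artifacts plus a self-describing run manifest
#' (`manifest.yaml`). A rerun with the same config and seed is
#' bit-identical for all text outputs.
#'
#' @param config either a YAML file path or a nested list; unspecified
#'   fields fall back to [default_pipeline_config()]. With a `simulate`
#'   block (a list of [sim_config()] overrides, possibly empty) the
#'   pipeline generates its own inputs; otherwise `paths$genome` and the
#'   named `paths$sam` list are required.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_pipeline_config(), config)
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "clipnucleo",
                   version = as.character(utils::packageVersion("clipnucleo")),
                   config = config, stages = list())
  truth <- NULL
  model <- NULL

  if (!is.null(config$simulate)) {
    scfg <- do.call(sim_config, config$simulate)
    gm <- make_genome(scfg, seed)
    genome <- gm$genome
    model <- gm$model
    truth <- plant_truth(genome, model, scfg, seed + 1L)
    simout <- simulate_clip(genome, truth, seed + 2L,
                            file.path(out, "sim"))
    fastq <- simout$fastq
    sam <- simout$sam
    snp_mask_path <- simout$vcf
    barcodes <- scfg$barcodes
    manifest$stages$simulate <- list(
      n_reads = nrow(simout$sim$reads),
      n_m6a_planted = nrow(truth$m6a),
      n_anchors_planted = nrow(truth$anchors),
      n_snps_planted = nrow(truth$snps))
  } else {
    genome <- read_fasta(config$paths$genome)
    fastq <- config$paths$fastq
    sam <- config$paths$sam
    snp_mask_path <- config$paths$snp_mask
    barcodes <- config$preprocess$barcodes
  }

  # preprocess + per-sample unique-tag alignments
  aln_all <- read_alignments(sam, genome)
  samples <- list()
  if (!is.null(fastq) && !is.null(barcodes)) {
    pp <- preprocess_reads(read_fastq(fastq), barcodes,
                           config$preprocess$min_len)
    manifest$stages$preprocess <- list(
      summary = pp$summary, n_unassigned = pp$n_unassigned)
    for (s in names(pp$samples))
      samples[[s]] <- subset_alignments(aln_all, pp$samples[[s]]$read_id)
  } else {
    samples[[config$m6a_sample]] <- aln_all
  }

  snp_mask <- if (!is.null(snp_mask_path))
    read_interval_mask(snp_mask_path, genome) else
      data.frame(contig = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 label = character(0))

  tallies <- list(); calls <- list()
  for (s in names(samples)) {
    tl <- tally_alignments(samples[[s]], genome)
    tallies[[s]] <- tl
    write_coverage_bedgraph(tl, file.path(out, paste0(s, "_coverage.bedgraph")))
    cims <- mask_known_snps(
      call_cims(tl, config$cims$sub_type, config$cims$n_perm, seed + 3L),
      snp_mask)
    cits <- call_cits(tl)
    write_sites_bed(cims, file.path(out, paste0(s, "_cims.bed")), genome)
    write_sites_bed(cits, file.path(out, paste0(s, "_cits.bed")), genome)
    calls[[s]] <- list(cims = cims, cits = cits)
    manifest$stages[[paste0("sitecall_", s)]] <- list(
      n_unique_tags = tl$lib_size, n_cims_candidates = nrow(cims),
      n_cits_tested = nrow(cits))
  }

  results <- list()
  ms <- config$m6a_sample
  if (ms %in% names(calls)) {
    m6a_cims <- call_m6a_from_cims(calls[[ms]]$cims, genome,
                                   config$m6a$max_ratio, config$m6a$fdr)
    m6a_cits <- call_m6a_from_cits(calls[[ms]]$cits, genome,
                                   config$cits$alpha, config$cits$use_raw_p)
    m6a <- combine_m6a_calls(m6a_cims, m6a_cits)
    write_sites_bed(m6a, file.path(out, "m6a.bed"), genome)
    results$m6a <- m6a
    manifest$stages$m6a <- list(
      n_cims_based = nrow(m6a_cims), n_cits_based = nrow(m6a_cits),
      n_combined = nrow(m6a))
  }
  fs <- config$footprint_sample
  if (fs %in% names(calls)) {
    fp <- call_reader_footprints(calls[[fs]]$cims, calls[[fs]]$cits, genome,
                                 config$footprints$fdr,
                                 config$footprints$alpha,
                                 config$cits$use_raw_p,
                                 config$footprints$cits_require_a)
    write_sites_bed(fp, file.path(out, "footprints.bed"), genome)
    results$footprints <- fp
    manifest$stages$footprints <- list(
      n_cims_based = sum(fp$evidence == "CIMS"),
      n_cits_based = sum(fp$evidence == "CITS"), n_total = nrow(fp))
  }

  ic <- config$integrate
  if (!is.null(results$m6a) && !is.null(results$footprints) &&
      nrow(results$m6a) > 0 && nrow(results$footprints) > 0) {
    ov <- overlap_sites(results$m6a, results$footprints, ic$tolerance)
    utils::write.table(
      data.frame(set = c("m6a_only", "overlap", "footprint_only"),
                 n = c(ov$n_a_only, ov$n_overlap, ov$n_b_only)),
      file.path(out, "venn.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    results$venn <- ov

    pr <- suppressWarnings(
      metagene_profile(tallies[[fs]], results$m6a, ic$halfwidth))
    utils::write.table(
      data.frame(offset = pr$offsets, intensity = pr$intensity),
      file.path(out, "profile_reader_at_m6a.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    results$profile_reader_at_m6a <- pr
    pr2 <- suppressWarnings(
      metagene_profile(tallies[[ms]], results$footprints, ic$halfwidth))
    utils::write.table(
      data.frame(offset = pr2$offsets, intensity = pr2$intensity),
      file.path(out, "profile_m6a_at_footprints.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    results$profile_m6a_at_footprints <- pr2

    en <- suppressWarnings(
      motif_enrichment(results$footprints, genome, ic$motif,
                       ic$n_bg_per_fg, ic$bg_mode, seed + 4L))
    utils::write.table(
      data.frame(motif = en$motif, p = en$p, score_ratio = en$ratio,
                 n_fg = length(en$fg_scores), n_bg = length(en$bg_scores)),
      file.path(out, "motif_enrichment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    results$motif <- en

    splice <- if (!is.null(model)) model$splice_sites else
      if (!is.null(config$paths$splice_sites)) {
        iv <- read_interval_mask(config$paths$splice_sites, genome)
        data.frame(contig = iv$contig, pos = iv$start, strand = iv$strand)
      } else NULL
    if (!is.null(splice)) {
      sp <- splice_proximity_test(splice, results$m6a, tallies[[fs]],
                                  ic$flank, ic$intensity_window)
      utils::write.table(
        data.frame(group = c("near", "not_near"),
                   n = c(sp$n_near, sp$n_far),
                   mean_intensity = c(mean(sp$sites$intensity[sp$sites$near]),
                                      mean(sp$sites$intensity[!sp$sites$near])),
                   p = sp$p),
        file.path(out, "splice_test.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      results$splice <- sp
    }
  }

  if (!is.null(truth)) {
    sc <- list()
    if (!is.null(results$m6a))
      sc$m6a <- score_against_truth(
        results$m6a, truth$m6a[c("contig", "pos", "strand")], 0L)
    if (!is.null(results$footprints))
      sc$footprints <- score_against_truth(
        results$footprints, truth$anchors[c("contig", "pos", "strand")], 5L)
    manifest$stages$scoring <- sc
    results$scores <- sc
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.yaml$", files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  manifest$results <- results
  invisible(manifest)
}
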