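# End-to-end pipeline: simulate -> quantify -> discover -> cohort stats,
# driven by a single config, fully reproducible by seed.

#' Default pipeline configuration
#'
#' A small demo-scale design: 5 tumour-normal pairs, 20,000 single-end reads
#' per sample for quantification, plus one deep paired-end sample expressing
#' every novel transcript class for junction discovery.
#'
#' @return Nested list understood by [run_pipeline()]; serialisable to YAML.
#' @export
default_pipeline_config <- function() {
  list(
    locus = list(seed_offset = 0L),
    cohort = list(n_pairs = 5L, n_reads = 20000L),
    quantify = list(strand_mode = "both"),
    discovery = list(
      n_reads = 20000L, read_len = 100L, paired = TRUE,
      fragment_len_mean = 150, fragment_len_sd = 15,
      min_overlap = 10L, max_mismatch_rate = 0, min_support = 1L,
      novel_abundance = 1
    )
  )
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return Config list merged over [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  modifyList(default_pipeline_config(), cfg)
}

#' Run the full pipeline
#'
#' Stages: build the locus (FASTA, probe TSV, junction TSV/BED); simulate a
#' paired cohort and write FASTQ + truth JSON; quantify every sample against
#' the probe set and write per-sample and cohort TSVs; simulate and run
#' junction discovery on a sample expressing all novel classes (calls
#' TSV/BED); compute the cohort deregulation report (TSV/JSON).  A manifest of
#' every artifact with its MD5 checksum is written last; identical config and
#' seed give identical checksums.
#'
#' @param config Config list (see [default_pipeline_config()]) or a YAML/JSON
#'   path.
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed propagated to every stochastic stage.
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir, seed = 1L,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- as.integer(seed)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    if (!quiet) message("created output directory ", out_dir)
  }
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "), ...)
  artifacts <- character(0)
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  say("stage locus: building locus model")
  locus <- build_locus(seed = seed + (config$locus$seed_offset %||% 0L))
  probes <- default_probe_set(locus)
  write_locus_fasta(locus, keep(file.path(out_dir, "locus.fasta")))
  write_locus_fasta(locus, keep(file.path(out_dir, "transcripts.fasta")),
                    transcripts = enumerate_all_transcripts(locus))
  write_probes_tsv(probes, keep(file.path(out_dir, "probes.tsv")))
  write_junctions_tsv(locus, keep(file.path(out_dir, "junctions.tsv")))
  write_junctions_bed(locus, keep(file.path(out_dir, "junctions.bed")))

  say("stage simulate: ", config$cohort$n_pairs, " pairs, ",
      config$cohort$n_reads, " reads/sample")
  design <- cohort_design(n_pairs = config$cohort$n_pairs,
                          n_reads = config$cohort$n_reads)
  sp <- sim_params(n_reads = config$cohort$n_reads)
  cohort <- simulate_cohort(locus, design, seed = seed, emit = "reads",
                            params = sp, out_dir = out_dir, probes = probes)
  for (s in cohort$samples) for (f in s$files) keep(f)
  write_truth_json(cohort, keep(file.path(out_dir, "truth.json")))

  say("stage quantify: scanning ", length(cohort$samples), " samples")
  samples <- lapply(cohort$samples, function(s) {
    sc <- quantify_sample(s$files, probes, sample_id = s$sample_id,
                          group = s$group, pair_id = s$pair_id,
                          strand_mode = config$quantify$strand_mode)
    df <- data.frame(probe = names(sc$raw), raw = unname(sc$raw),
                     normalized = unname(sc$normalized))
    utils::write.table(df, keep(file.path(out_dir, paste0(s$sample_id, ".counts.tsv"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc
  })
  tab <- build_expression_table(samples)
  write_expression_tsv(tab, keep(file.path(out_dir, "cohort_counts.tsv")))

  say("stage discover: paired-end sample expressing all junction classes")
  dcfg <- config$discovery
  ab <- stats::setNames(rep(dcfg$novel_abundance, length(NOVEL_CLASSES)),
                        NOVEL_CLASSES)
  ab <- c(v1 = dcfg$novel_abundance, v2 = dcfg$novel_abundance,
          v3 = dcfg$novel_abundance, ab)
  dsim <- simulate_sample(
    locus, ab,
    sim_params(read_len = dcfg$read_len, paired = isTRUE(dcfg$paired),
               fragment_len_mean = dcfg$fragment_len_mean,
               fragment_len_sd = dcfg$fragment_len_sd,
               n_reads = dcfg$n_reads),
    seed = seed + 1L, out_prefix = file.path(out_dir, "discovery_sample"),
    probes = probes, sample_id = "discovery_sample")
  for (f in dsim$files) keep(f)
  calls <- discover(list(r1 = dsim$reads$r1, r2 = dsim$reads$r2), locus,
                    paired = isTRUE(dcfg$paired),
                    min_overlap = dcfg$min_overlap,
                    max_mismatch_rate = dcfg$max_mismatch_rate,
                    min_support = dcfg$min_support)
  write_calls_tsv(calls, keep(file.path(out_dir, "junction_calls.tsv")))
  write_calls_bed(calls, locus, keep(file.path(out_dir, "junction_calls.bed")))

  say("stage cohort-stats: paired tests and correlations")
  report <- deregulation_report(tab)
  write_report(report, tsv_path = keep(file.path(out_dir, "report.tsv")),
               json_path = keep(file.path(out_dir, "report.json")))

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  say("done: ", nrow(manifest), " artifacts")
  invisible(manifest)
}
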