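## End-to-end orchestration of the synthetic capture experiment:
## simulate -> process reads -> collapse/classify -> annotate -> validate ->
## enrichment & saturation statistics -> report bundle.

#' Build a run configuration
#'
#' All knobs of the synthetic experiment and the analysis thresholds, with
#' defaults encoding the study conditions: a 20-gene annotation with up to 8
#' isoforms per gene, expression spanning 6 orders of magnitude, capture at
#' p_on = 0.5 over background 0.005 with the 35/45-nt overlap knee, 20,000
#' reads at 80% full-length and a 2% chimera rate across 7 sample barcodes
#' and 96 dual-barcode pairs, and a fifth of alternative isoforms withheld
#' from the classification reference so that genuine novelty exists.
#'
#' @param seed Global seed; expanded into independent per-stage seeds.
#' @param ... Overrides of any default listed below.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    schema = "capiso-run/1",
    seed = as.integer(seed),
    n_genes = 20L,
    isoforms_per_gene_range = c(1L, 8L),
    exons_per_transcript_range = c(3L, 9L),
    exon_len_range = c(80L, 300L),
    intron_len_range = c(80L, 400L),
    polya_rate = 0.7,
    log10_range = 6,
    n_targets = 8L,
    target_bias = "low_abundance",
    p_on = 0.5, p_bg = 0.005,
    overlap_full = 45L, overlap_floor = 35L,
    n_reads = 20000L,
    fl_rate = 0.8,
    chimera_rate = 0.02,
    n_samples = 7L,
    n_barcode_pairs = 96L,
    novel_isoform_fraction = 0.2,
    junction_mean_depth = 5e5,
    min_overlap = 50L,
    min_coverage = 0.99, min_identity = 0.95,
    min_junction_support = 3L,
    polya_window = c(5L, 25L),
    saturation_iterations = 100L,
    saturation_depth_fractions = c(0.05, 0.1, 0.25, 0.5, 1))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ",
                             paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$min_overlap >= 1L, cfg$min_coverage >= 0, cfg$min_coverage <= 1,
            cfg$min_identity >= 0, cfg$min_identity <= 1,
            cfg$min_junction_support >= 0L,
            cfg$polya_window[1L] < cfg$polya_window[2L],
            cfg$saturation_iterations >= 1L,
            cfg$novel_isoform_fraction >= 0, cfg$novel_isoform_fraction <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` invisibly / the re-read `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "capiso-run/1"))
    stop("unrecognised config schema: ", raw$schema)
  raw$schema <- NULL
  seed <- raw$seed; raw$seed <- NULL
  do.call(run_config, c(list(seed = seed), raw))
}

pipeline_stage <- function(name, quiet, expr) {
  if (!quiet) message(format(Sys.time(), "%H:%M:%OS2"), " [", name, "] start")
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (!quiet) message(format(Sys.time(), "%H:%M:%OS2"), " [", name, "] done")
  res
}

#' Run the full synthetic capture pipeline
#'
#' Simulates the experiment defined by `config`, processes the reads
#' (full-length filter, demultiplexing, collapse, dual-barcode chimera
#' calls), classifies isoforms against the withheld-novelty reference
#' annotation, annotates features, applies the short-read junction
#' validation filter, and computes enrichment, saturation and coverage
#' statistics.  Two runs with an identical config produce identical outputs.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, all inputs and
#'   results are written there (GTF/FASTA/BED/bedGraph/TSV/JSON + manifest).
#' @param quiet Suppress stage log messages (default TRUE).
#' @return A report bundle (list) with all intermediate and final objects.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL, quiet = TRUE) {
  set.seed(config$seed)
  ss <- sample.int(.Machine$integer.max - 1L, 12L)

  sim <- pipeline_stage("simulate_annotation", quiet,
    simulate_annotation(
      n_genes = config$n_genes,
      isoforms_per_gene_range = config$isoforms_per_gene_range,
      exons_per_transcript_range = config$exons_per_transcript_range,
      exon_len_range = config$exon_len_range,
      intron_len_range = config$intron_len_range,
      polya_rate = config$polya_rate, seed = ss[1L]))
  annotation <- sim$annotation
  genome <- sim$genome

  ## withhold a fraction of alternative isoforms from the reference so the
  ## classifier can encounter genuinely novel structures
  set.seed(ss[2L])
  alt <- names(annotation$transcripts)[!vapply(annotation$transcripts,
    function(t) "appris_principal" %in% t$tags, TRUE)]
  withheld <- sort(sample(alt, round(config$novel_isoform_fraction * length(alt))))
  reference <- subset_annotation(
    annotation, setdiff(names(annotation$transcripts), withheld))

  expression <- pipeline_stage("simulate_expression", quiet,
    simulate_expression(annotation, config$log10_range, seed = ss[4L]))

  ## targets are drawn from the lower-abundance half of genes, mirroring the
  ## selection of low-to-moderate abundance genes for capture (the setting in
  ## which enrichment is worthwhile); set target_bias = "uniform" to disable
  set.seed(ss[3L])
  gene_ab <- vapply(names(annotation$genes), function(g)
    sum(expression[annotation$genes[[g]]]), 0)
  pool <- if (identical(config$target_bias, "low_abundance")) {
    low <- names(gene_ab)[gene_ab <= stats::median(gene_ab)]
    if (length(low) >= config$n_targets) low else names(gene_ab)
  } else names(gene_ab)
  targets <- sort(sample(pool, config$n_targets))
  template <- select_representative(annotation, mode = "appris")[targets]
  probe_tpm <- setNames(10^runif(length(targets), -1, 2), targets)
  design <- capture_design(targets, template, probe_tpm, annotation)
  cmodel <- capture_model(config$p_on, config$p_bg,
                          config$overlap_full, config$overlap_floor)
  capture <- pipeline_stage("simulate_capture", quiet,
    simulate_capture(expression, design, cmodel, annotation))
  capturant <- capture$profile

  sample_barcodes <- sprintf("bc%02d", seq_len(config$n_samples))
  pairs <- dual_barcode_pair_table(config$n_barcode_pairs)
  reads <- pipeline_stage("simulate_long_reads", quiet,
    simulate_long_reads(capturant, annotation, config$n_reads,
                        fl_rate = config$fl_rate,
                        chimera_rate = config$chimera_rate,
                        sample_barcodes = sample_barcodes,
                        dual_barcode_pairs = pairs, seed = ss[5L]))

  fl_reads <- reads[classify_full_length(reads), , drop = FALSE]
  attr(fl_reads, "pairs") <- pairs
  demux <- demultiplex(reads, sample_barcodes)
  isoforms <- pipeline_stage("collapse_reads", quiet, collapse_reads(fl_reads))
  isoforms <- filter_alignments(isoforms, config$min_coverage,
                                config$min_identity)
  records <- pipeline_stage("classify", quiet,
    classify_isoforms(isoforms, reference, genome = genome))
  novel_flag <- setNames(
    !records$category %in% c("FSM", "ISM", "mono-exon-known", "intergenic"),
    records$isoform_id)
  chimera <- pipeline_stage("chimera", quiet,
    call_isoform_chimeras(isoforms, fl_reads, novel = novel_flag,
                          pairs = pairs))

  junction_counts <- pipeline_stage("short_read_junctions", quiet,
    simulate_short_read_junction_counts(expression, annotation,
                                        config$junction_mean_depth,
                                        seed = ss[6L]))
  records <- validate_novel_isoforms(records, junction_counts,
                                     config$min_junction_support)

  peaks <- simulate_cage_peaks(annotation, seed = ss[7L])
  cons <- simulate_conservation_track(annotation, seed = ss[8L])
  track_path <- tempfile(fileext = ".bedgraph")
  write_track(cons, track_path)
  track <- read_track(track_path)
  unlink(track_path)
  features <- pipeline_stage("features", quiet,
    annotate_features(isoforms, peaks, genome, track,
                      polya_window = config$polya_window))

  enrichment <- pipeline_stage("enrichment", quiet,
    enrichment_report(as.numeric(expression) |> setNames(names(expression)),
                      as.numeric(capturant) |> setNames(names(capturant)),
                      annotation, targets))
  ## closed-form prediction of the capturant on-target rate from the capture
  ## model and pre-capture profile (deterministic capture)
  eff <- capture$efficiency
  tgt_tx <- unlist(annotation$genes[targets], use.names = FALSE)
  pre <- as.numeric(expression); names(pre) <- names(expression)
  predicted_capturant_rate <-
    sum(pre[tgt_tx] * eff[tgt_tx]) / sum(pre * eff)

  iso_of_read <- setNames(
    rep(vapply(isoforms, `[[`, "", "isoform_id"),
        vapply(isoforms, function(x) length(x$member_reads), 0L)),
    unlist(lapply(isoforms, `[[`, "member_reads"), use.names = FALSE))
  assigned <- fl_reads$read_id %in% names(iso_of_read)
  ra_iso <- iso_of_read[fl_reads$read_id[assigned]]
  rec_by_iso <- records[match(ra_iso, records$isoform_id), ]
  read_assignments <- data.frame(
    read_id = fl_reads$read_id[assigned],
    gene_id = ifelse(is.na(rec_by_iso$matched_gene_id), "unmatched",
                     rec_by_iso$matched_gene_id),
    isoform_id = unname(ra_iso),
    fsm = rec_by_iso$category == "FSM",
    stringsAsFactors = FALSE)
  depths <- unique(pmax(1L, as.integer(round(
    config$saturation_depth_fractions * nrow(read_assignments)))))
  saturation <- pipeline_stage("saturation", quiet,
    discovery_curve(read_assignments, depths,
                    n_iterations = config$saturation_iterations,
                    seed = ss[9L]))

  fl_fracs <- gene_abundance_fractions(
    tapply_counts(read_assignments$gene_id, names(annotation$genes),
                  annotation), annotation)
  on_target_fl <- on_target_rate(fl_fracs, targets)

  basic <- filter_basic_coding(annotation)
  reps_appris <- select_representative(basic, mode = "appris")
  reps_random <- select_representative(basic, mode = "random", seed = ss[10L])
  coverage <- list(
    appris_exonic = coverage_estimate(basic, reps_appris, config$min_overlap),
    appris_span = coverage_estimate(basic, reps_appris, config$min_overlap,
                                    span = TRUE),
    random_exonic = coverage_estimate(basic, reps_random, config$min_overlap))

  bundle <- list(
    config = config, annotation = annotation, reference = reference,
    withheld = withheld, genome = genome, design = design,
    capture_model = cmodel, expression = expression, capturant = capturant,
    capture_efficiency = eff, reads = reads, demux = demux,
    isoforms = isoforms, records = records, features = features,
    chimera = chimera, junction_counts = junction_counts,
    peaks = peaks, conservation = cons,
    enrichment = enrichment,
    predicted_capturant_rate = predicted_capturant_rate,
    on_target_fl = on_target_fl,
    read_assignments = read_assignments, saturation = saturation,
    rank_abundance = rank_abundance_table(
      enrichment$per_gene_fraction, targets),
    coverage = coverage,
    recovery = recovery_statistics(records, reference,
                                   probe_tpm = design$probe_tpm,
                                   expression = expression),
    novelty = novelty_summary(records, reference))
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

## per-gene FL read counts as a transcript-keyed stand-in is not needed;
## build gene fractions straight from gene counts
tapply_counts <- function(gene_ids, all_genes, annotation) {
  counts <- table(factor(gene_ids[gene_ids %in% all_genes],
                         levels = all_genes))
  ## expand to transcript level by putting each gene's count on its first
  ## transcript, so gene_abundance_fractions() sums back per gene
  first_tx <- vapply(annotation$genes, `[[`, "", 1L)
  setNames(as.numeric(counts), first_tx[names(counts)])
}

#' Write a pipeline bundle to disk
#'
#' Serialises all simulated inputs and results of [run_pipeline()] to plain
#' text files (GTF, FASTA, BED, bedGraph, TSV, JSON) plus a YAML manifest;
#' used for the end-to-end determinism guarantee.
#'
#' @param bundle A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_gtf(bundle$annotation, p("annotation.gtf"))
  write_gtf(bundle$reference, p("reference.gtf"))
  write_genome(bundle$genome, p("genome.fa"))
  write_tsv_table(data.frame(transcript_id = names(bundle$expression),
                             tpm = as.numeric(bundle$expression)),
                  p("expression.tsv"))
  write_tsv_table(data.frame(transcript_id = names(bundle$capturant),
                             tpm = as.numeric(bundle$capturant),
                             efficiency = unname(bundle$capture_efficiency)),
                  p("capturant.tsv"))
  reads_out <- bundle$reads
  attr(reads_out, "pairs") <- NULL
  write_tsv_table(as.data.frame(reads_out), p("reads.tsv"))
  write_bed12(bundle$isoforms, p("isoforms.bed12"))
  rec <- merge(bundle$records, bundle$features, by = "isoform_id", sort = TRUE)
  write_tsv_table(rec, p("classification.tsv"))
  write_tsv_table(bundle$junction_counts, p("junction_counts.tsv"))
  write_bed6(bundle$peaks, p("cage_peaks.bed"))
  write_track(bundle$conservation, p("conservation.bedgraph"))
  write_tsv_table(bundle$chimera$per_isoform, p("chimera_per_isoform.tsv"))
  jsonlite::write_json(list(
    n_reads = bundle$chimera$n_reads,
    n_concordant = bundle$chimera$n_concordant,
    n_discordant = bundle$chimera$n_discordant,
    nonchimeric_rate_all = bundle$chimera$nonchimeric_rate_all,
    nonchimeric_rate_novel = bundle$chimera$nonchimeric_rate_novel),
    p("chimera_report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    on_target_input = bundle$enrichment$on_target_input,
    on_target_capturant = bundle$enrichment$on_target_capturant,
    on_target_fl = bundle$on_target_fl,
    fold_enrichment = bundle$enrichment$fold_enrichment,
    predicted_capturant_rate = bundle$predicted_capturant_rate),
    p("enrichment.json"), auto_unbox = TRUE, digits = NA)
  write_tsv_table(bundle$saturation$curve, p("saturation_curve.tsv"))
  write_tsv_table(bundle$rank_abundance, p("rank_abundance.tsv"))
  write_tsv_table(bundle$coverage$appris_exonic$per_gene, p("coverage_per_gene.tsv"))
  jsonlite::write_json(list(
    appris_exonic = bundle$coverage$appris_exonic$fraction_covered,
    appris_span = bundle$coverage$appris_span$fraction_covered,
    random_exonic = bundle$coverage$random_exonic$fraction_covered),
    p("coverage.json"), auto_unbox = TRUE, digits = NA)
  write_run_config(bundle$config, p("manifest.yaml"))
  invisible(outdir)
}

#' Human-readable summary of a pipeline bundle
#'
#' Emits the headline statistics of the run (on-target rates, fold
#' enrichment, category and novelty proportions, recovery, chimera rates,
#' saturation curve); sections whose inputs are missing from the bundle are
#' marked absent.
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of report lines (also printable via `cat`).
#' @export
make_report <- function(bundle) {
  fmt_pct <- function(x) sprintf("%.2f%%", 100 * x)
  lines <- c("== capiso run report ==", "")
  if (!is.null(bundle$enrichment)) {
    e <- bundle$enrichment
    lines <- c(lines, "[enrichment]",
      sprintf("  on-target rate (TPM): input %s -> capturant %s",
              fmt_pct(e$on_target_input), fmt_pct(e$on_target_capturant)),
      sprintf("  on-target rate (FL reads): %s", fmt_pct(bundle$on_target_fl)),
      sprintf("  fold enrichment: %.1f", e$fold_enrichment), "")
  } else lines <- c(lines, "[enrichment] absent", "")
  if (!is.null(bundle$records)) {
    tab <- table(bundle$records$category)
    nv <- bundle$novelty
    lines <- c(lines, "[classification]",
      sprintf("  %d isoforms: %s", nrow(bundle$records),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")),
      sprintf("  novelty: sites %s, junctions %s, isoforms %s",
              fmt_pct(nv$site_novelty), fmt_pct(nv$junction_novelty),
              fmt_pct(nv$isoform_novelty)),
      sprintf("  validated novel isoforms: %d / %d",
              sum(bundle$records$validated &
                    !bundle$records$category %in%
                      c("FSM", "ISM", "mono-exon-known", "intergenic")),
              sum(!bundle$records$category %in%
                    c("FSM", "ISM", "mono-exon-known", "intergenic"))), "")
  } else lines <- c(lines, "[classification] absent", "")
  if (!is.null(bundle$chimera)) {
    lines <- c(lines, "[chimeras]",
      sprintf("  non-chimeric isoform rate: all %s, novel %s",
              fmt_pct(bundle$chimera$nonchimeric_rate_all),
              if (is.na(bundle$chimera$nonchimeric_rate_novel)) "absent"
              else fmt_pct(bundle$chimera$nonchimeric_rate_novel)), "")
  } else lines <- c(lines, "[chimeras] absent", "")
  if (!is.null(bundle$features)) {
    f <- bundle$features
    lines <- c(lines, "[features]",
      sprintf("  5' within CAGE peak: %s", fmt_pct(mean(f$within_cage))),
      sprintf("  polyA motif found: %s", fmt_pct(mean(f$polya_motif_found))), "")
  } else lines <- c(lines, "[features] absent", "")
  if (!is.null(bundle$coverage)) {
    lines <- c(lines, "[capture coverage]",
      sprintf("  appris/exonic: %s; appris/span: %s; random/exonic: %s",
              fmt_pct(bundle$coverage$appris_exonic$fraction_covered),
              fmt_pct(bundle$coverage$appris_span$fraction_covered),
              fmt_pct(bundle$coverage$random_exonic$fraction_covered)), "")
  } else lines <- c(lines, "[capture coverage] absent", "")
  if (!is.null(bundle$saturation)) {
    cv <- bundle$saturation$curve
    lines <- c(lines, "[saturation]",
      sprintf("  depth %d: %.1f genes, %.1f isoforms", cv$depth,
              cv$mean_unique_genes, cv$mean_unique_isoforms), "")
  } else lines <- c(lines, "[saturation] absent", "")
  lines
}
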