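# End-to-end drivers: run the whole discovery + characterization pipeline on
# fragment libraries, and the simulate-then-validate harness that scores the
# pipeline against the generator's truth table.

#' Run the enhancer discovery and characterization pipeline
#'
#' Executes chromosome filtering, per-replicate peak calling, replicate
#' consensus, genomic classification, matched-control construction, GC and
#' repeat composition statistics, and motif enrichment, writing the
#' interface files of each stage plus a machine-readable run manifest.
#'
#' @param genome A [Genome].
#' @param annotation A [GeneAnnotation].
#' @param libraries List of per-replicate `list(cdna=, input=)`
#'   [FragmentLibrary] pairs.
#' @param pwms List of [pwm] motifs to test (optional; skip motif stage
#'   when `NULL`).
#' @param params A [peak_call_params()].
#' @param n_control_sets,control_band,control_max_n,control_max_attempts
#'   Control-sampling parameters.
#' @param alpha Significance level for the composition consensus procedure.
#' @param seed Seed for control sampling.
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @return List with per-stage results: `replicate_peaks`, `consensus`,
#'   `classification`, `controls`, `gc_test`, `dinucleotide`, `motifs`,
#'   `coverage`, `compartment`, `counts` (per-stage counters).
#' @export
run_pipeline <- function(genome, annotation, libraries, pwms = NULL,
                         params = peak_call_params(), n_control_sets = 10L,
                         control_band = 5e5, control_max_n = 0.01,
                         control_max_attempts = 1000L, alpha = 0.001,
                         seed = 1L, outdir = NULL) {
  counts <- list()
  libraries <- lapply(libraries, function(rep_pair)
    lapply(rep_pair, filter_chromosomes, genome = genome))
  counts$fragments_after_filter <- vapply(libraries, function(p)
    p$cdna$total_count + p$input$total_count, numeric(1))

  rep_peaks <- lapply(libraries, function(p)
    call_peaks(p$cdna, p$input, genome, params))
  counts$peaks_per_replicate <- vapply(rep_peaks, length, integer(1))

  consensus <- consensus_peaks(rep_peaks, params)
  counts$consensus <- length(consensus)

  classification <- if (length(consensus))
    classify_peaks(consensus, annotation) else NULL

  controls <- NULL
  gc_test <- NULL
  dinuc <- NULL
  motif_res <- NULL
  if (length(consensus) > 0) {
    controls <- build_control_sets(
      consensus, genome, annotation, peaks = consensus,
      n_sets = n_control_sets, band = control_band,
      max_n_fraction = control_max_n,
      max_attempts = control_max_attempts, seed = seed)
    enh_seqs <- interval_sequences(consensus, genome)
    ctrl_seqs <- lapply(controls$sets, interval_sequences, genome = genome)
    gc_test <- consensus_compare(gc_content(enh_seqs),
                                 lapply(ctrl_seqs, gc_content),
                                 alpha = alpha, metric = "gc_content")
    dinuc <- dinucleotide_enrichment(enh_seqs, ctrl_seqs)
    if (!is.null(pwms))
      motif_res <- consensus_motif_enrichment(pwms, enh_seqs, ctrl_seqs)
  }
  coverage <- lapply(libraries, function(p)
    list(cdna = coverage_median(p$cdna, genome),
         input = coverage_median(p$input, genome)))
  compartment <- compartment_summary(consensus, genome)

  res <- list(replicate_peaks = rep_peaks, consensus = consensus,
              classification = classification, controls = controls,
              gc_test = gc_test, dinucleotide = dinuc, motifs = motif_res,
              coverage = coverage, compartment = compartment,
              counts = counts)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(res$replicate_peaks)) {
    pk <- res$replicate_peaks[[r]]
    out <- granges(pk)
    if (length(pk)) {
      mcols(out)$name <- sprintf("rep%d_peak_%04d", r, seq_along(pk))
      mcols(out)$score <- signif(mcols(pk)$enrichment, 6)
    }
    write_bed(out, file.path(outdir, sprintf("peaks_rep%d.bed", r)))
  }
  cons <- res$consensus
  out <- granges(cons)
  if (length(cons)) {
    mcols(out)$name <- mcols(cons)$name
    mcols(out)$score <- signif(mcols(cons)$activity, 6)
  }
  write_bed(out, file.path(outdir, "consensus_enhancers.bed"))
  if (length(cons)) {
    tab <- data.frame(name = mcols(cons)$name,
                      chrom = as.character(seqnames(cons)),
                      start0 = start(cons) - 1L, end0 = end(cons),
                      activity = mcols(cons)$activity)
    if (!is.null(res$classification))
      tab <- cbind(tab, res$classification)
    write.table(tab, file.path(outdir, "consensus_enhancers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$controls))
    write_control_sets(res$controls, file.path(outdir, "controls"))
  if (!is.null(res$dinucleotide))
    write.table(res$dinucleotide,
                file.path(outdir, "dinucleotide_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$motifs))
    write.table(res$motifs[, c("motif", "n_enriched", "consensus")],
                file.path(outdir, "motif_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    counts = res$counts,
    compartment = res$compartment,
    gc_verdict = if (!is.null(res$gc_test)) res$gc_test$verdict else NA,
    coverage_input_median = vapply(res$coverage, function(x)
      x$input$global, numeric(1)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Simulate a study and validate the pipeline against the truth table
#'
#' Runs [simulate_genome()], [simulate_fragments()] and [run_pipeline()] at
#' the given configuration, then joins the pipeline output to the planted
#' truth: sensitivity (planted enhancers recovered by at least one consensus
#' call), unplanted (false-positive) consensus calls, class-mix recovery,
#' the GC contrast, dinucleotide enrichment signs and planted-motif
#' consensus recovery.
#'
#' @param config A [simulation_config()].
#' @param pwms Motifs to test (default [demo_motifs()], which includes the
#'   planted motifs and four decoys).
#' @param outdir Optional output directory passed to [run_pipeline()].
#' @return List of class `ValidationReport`; see Details in the vignette.
#' @export
simulate_and_validate <- function(config = simulation_config(),
                                  pwms = demo_motifs(), outdir = NULL) {
  sim <- simulate_genome(config)
  libs <- simulate_fragments(sim$genome, sim$truth, config)
  null_mode <- config$enhancer_fold <= 1
  res <- run_pipeline(sim$genome, sim$annotation, libs,
                      pwms = if (null_mode) NULL else pwms,
                      seed = config$seed)
  planted <- sim$truth$enhancers
  cons <- res$consensus
  hits <- findOverlaps(planted, cons, ignore.strand = TRUE)
  recovered <- length(unique(queryHits(hits)))
  fp <- length(cons) - length(unique(subjectHits(hits)))
  class_mix <- if (!is.null(res$classification))
    table(res$classification$class) else NULL
  planted_ids <- vapply(config$planted_motifs, `[[`, "", "id")
  motif_recovered <- if (!is.null(res$motifs))
    sum(res$motifs$consensus[res$motifs$motif %in% planted_ids]) else NA
  motif_fp <- if (!is.null(res$motifs))
    sum(res$motifs$consensus[!res$motifs$motif %in% planted_ids]) else NA
  structure(list(
    null_mode = null_mode,
    n_planted = length(planted),
    n_consensus = length(cons),
    sensitivity = if (null_mode) NA_real_ else recovered / length(planted),
    false_positives = fp,
    class_mix = class_mix,
    gc_verdict = if (!is.null(res$gc_test)) res$gc_test$verdict else NA,
    gc_enhancer_mean = if (length(cons))
      mean(gc_content(interval_sequences(cons, sim$genome))) else NA_real_,
    gc_control_mean = if (!is.null(res$controls))
      mean(unlist(lapply(res$controls$sets, function(s)
        gc_content(interval_sequences(s, sim$genome))))) else NA_real_,
    dinucleotide = res$dinucleotide,
    motif_planted_recovered = motif_recovered,
    motif_unplanted_called = motif_fp,
    compartment = res$compartment,
    pipeline = res, sim = sim),
    class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("Validation report",
      if (x$null_mode) "(null screen: enhancer_fold = 1)", "\n")
  cat(sprintf("  planted %d, consensus calls %d, sensitivity %s, unplanted calls %d\n",
              x$n_planted, x$n_consensus,
              ifelse(is.na(x$sensitivity), "NA",
                     sprintf("%.3f", x$sensitivity)), x$false_positives))
  if (!is.na(x$gc_verdict))
    cat(sprintf("  GC: %.3f (enhancers) vs %.3f (controls), verdict %s\n",
                x$gc_enhancer_mean, x$gc_control_mean, x$gc_verdict))
  if (!is.null(x$dinucleotide))
    cat("  dinucleotide log2 FE:",
        paste(sprintf("%s=%.2f", x$dinucleotide$class,
                      x$dinucleotide$log2_fe_mean), collapse = " "), "\n")
  if (!is.na(x$motif_planted_recovered))
    cat(sprintf("  motifs: %d planted recovered, %d unplanted called\n",
                x$motif_planted_recovered, x$motif_unplanted_called))
  invisible(x)
}
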