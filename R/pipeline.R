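#' Default run configuration
#'
#' Returns the pipeline defaults: quality filter at most 5 bases below
#' Q15, minimum merge overlap 11 nt, minimum unique coverage 2 for
#' consensus calls, 7-nt barcodes at minimum pairwise distance 3.
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(q_min = 15L, max_low = 5L, min_overlap = 11L, min_coverage = 2L,
       barcode_length = 7L, barcode_min_distance = 3L,
       end_tolerance = 2L, max_iter = 10L, seed = 1L)
}

#' Run the capture-to-consensus pipeline
#'
#' Orchestrates simulate (optional) -> demultiplex -> quality filter ->
#' merge -> iterative assembly -> contamination classification, writing
#' stage outputs and a machine-readable run report. Reruns with the same
#' configuration and seed are bit-identical.
#'
#' @param config configuration list or path to a YAML file. Recognised
#'   fields: `output_dir`; `seed`; parameter overrides (`q_min`,
#'   `max_low`, `min_overlap`, `min_coverage`, `end_tolerance`,
#'   `max_iter`); `reference` (FASTA path or literal sequence);
#'   `contaminant` (FASTA path or sequence, optional); either `simulate`
#'   (a list of [library_sim_config()] arguments except the references) or
#'   `fastq1`/`fastq2` plus `barcode`; `sample_name`.
#' @return object of class `run_report` (invisibly written to
#'   `output_dir/run_report.json`): stage counts, consensus statistics and
#'   the contamination report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_run_config()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  load_seq <- function(x) {
    if (is.null(x)) return(NULL)
    if (file.exists(x)) unname(read_fasta_seqs(x)[1L]) else toupper(x)
  }
  reference <- load_seq(config$reference) %||% stop("reference required")
  contaminant <- load_seq(config$contaminant)
  sample_name <- config$sample_name %||% "sample1"

  report <- list(config = config[setdiff(names(config), "output_dir")],
                 stages = list())
  stage_fail <- function(stage, err) {
    report$stages[[stage]] <- list(status = "failed",
                                   error = conditionMessage(err))
    report$failed_stage <- stage
    class(report) <- "run_report"
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }

  ## --- input stage: simulate or read ---------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$endogenous_ref <- reference
    if (!is.null(contaminant)) sim_args$contaminant_ref <- contaminant
    sim_args$seed <- config$seed
    cfg <- do.call(library_sim_config, sim_args)
    sim <- simulate_library(cfg)
    pairs <- sim$pairs
    barcode <- cfg$barcode
    write_truth_table(sim$truth, file.path(out_dir, "truth.tsv"))
  } else {
    pairs <- read_pairs(read_fastq(config$fastq1), read_fastq(config$fastq2))
    barcode <- toupper(config$barcode %||% stop("barcode required"))
    sim <- NULL
  }
  report$stages$input <- list(n_read_pairs = length(pairs))

  ## --- demultiplex ----------------------------------------------------
  dmx <- demultiplex(pairs, stats::setNames(barcode, sample_name))
  sample_pairs <- dmx$samples[[sample_name]]
  report$stages$demultiplex <- list(
    n_assigned = length(sample_pairs),
    n_unassigned = length(dmx$unassigned))

  ## --- quality filter -------------------------------------------------
  flt <- filter_read_pairs(sample_pairs, max_low = config$max_low,
                           q_min = config$q_min)
  report$stages$quality_filter <- list(n_in = flt$n_in, n_kept = flt$n_kept)

  ## --- merge ----------------------------------------------------------
  merged <- merge_pairs(flt$kept, min_overlap = config$min_overlap)
  report$stages$merge <- list(n_merged = merged$stats$n_merged,
                              n_unmerged = merged$stats$n_unmerged)
  write_fastq(read_set(merged$id, merged$seq, merged$qual),
              file.path(out_dir, "merged.fastq"))

  ## --- assembly -------------------------------------------------------
  asm <- iterate_assembly(merged, reference,
                          max_iter = config$max_iter,
                          min_coverage = config$min_coverage,
                          end_tolerance = config$end_tolerance)
  write_consensus(asm$consensus, sample_name,
                  fasta_path = file.path(out_dir, "consensus.fasta"),
                  tsv_path = file.path(out_dir, "consensus_positions.tsv"))
  cov <- coverage_stats(asm$pileup, reference)
  report$stages$assembly <- list(
    n_fragments = asm$n_fragments_in, n_mapped = asm$n_mapped,
    n_unique = asm$n_unique, n_iterations = asm$n_iterations,
    oscillated = asm$oscillated,
    n_called = sum(asm$consensus$status == "called"),
    n_low_coverage_N = sum(asm$consensus$status == "low_coverage_N"),
    n_ambiguous_N = sum(asm$consensus$status == "ambiguous_N"),
    median_coverage = cov$median_cov, mean_coverage = cov$mean_cov,
    gc_cov_pearson_r = cov$gc_cov_pearson_r)

  ## --- contamination --------------------------------------------------
  if (!is.null(contaminant)) {
    cr <- classify_fragments(merged, list(ingroup = reference), contaminant)
    report$stages$contamination <- list(
      n_endogenous = cr$n_endogenous, n_contaminant = cr$n_contaminant,
      n_noninformative = cr$n_noninformative, n_unmapped = cr$n_unmapped,
      p_cont = cr$p_cont, ci95_lo = unname(cr$ci95[["lo"]]),
      ci95_hi = unname(cr$ci95[["hi"]]),
      per_site_error = cr$per_site_error)
  }

  if (!is.null(sim)) report$truth_summary <- list(
    n_endogenous = sum(sim$truth$source == "endogenous"),
    n_contaminant = sum(sim$truth$source == "contaminant"),
    n_numt = sum(sim$truth$source == "numt"))

  class(report) <- "run_report"
  yaml::write_yaml(report$config, file.path(out_dir, "resolved_config.yaml"))
  jsonlite::write_json(report_to_json(report),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

report_to_json <- function(report) {
  ## strip non-serialisable bits (none at present) and return a plain list
  unclass(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  for (nm in names(x$stages)) {
    cat(" ", nm, ": ", paste(names(x$stages[[nm]]),
                             unlist(lapply(x$stages[[nm]], format)),
                             sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
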