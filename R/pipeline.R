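#' Compare the raw and consensus variant-calling pipelines
#'
#' Runs both arms of the UMI benchmark on one simulated experiment:
#' the "no UMI" arm collapses duplicates by coordinates only, the
#' consensus arm groups reads by UMI adjacency, calls and filters
#' molecular consensus reads. Both arms are piled up and called at the
#' same allele-fraction threshold; the consensus arm is additionally
#' called with the 8-oxoG mutation-specific threshold.
#'
#' @param sim a `sim_experiment` whose config carries spike-in variants.
#' @param threshold allele-fraction calling threshold (default 0.002).
#' @param oxog_threshold C>A/G>T threshold for the oxoG-aware call
#'   (default 0.003).
#' @param min_depth minimum depth per position (default 100).
#' @param filter_params a [consensus_filter_params()].
#' @return data.table with one row per arm ("raw", "consensus",
#'   "consensus_oxog"): tp, fp, fn, sensitivity, ppv, and
#'   tp_non_oxog (true positives among truth variants outside the
#'   C>A/G>T class).
#' @export
compare_consensus_raw <- function(sim, threshold = 0.002,
                                  oxog_threshold = 0.003,
                                  min_depth = 100L,
                                  filter_params =
                                    consensus_filter_params()) {
  truth <- as.data.table(sim$config$variants)
  if (is.null(truth) || nrow(truth) == 0) {
    stop("sim config carries no spike-in variants to evaluate")
  }
  ref_bases <- strsplit(sim$reference, "")[[1]]
  truth[, ref := ref_bases[pos + 1L]]
  truth[, is_oxog_class := (ref == "C" & alt == "A") |
          (ref == "G" & alt == "T")]

  arm_metrics <- function(calls, arm) {
    ev <- evaluate_calls(calls, truth)
    ov <- ev[ev$stratum == "overall"]
    called_keys <- paste(calls$pos[calls$called], calls$alt[calls$called])
    nox <- truth[truth$is_oxog_class == FALSE]
    data.table(arm = arm, tp = ov$tp, fp = ov$fp, fn = ov$fn,
               sensitivity = ov$sensitivity, ppv = ov$ppv,
               tp_non_oxog = sum(paste(nox$pos, nox$alt) %in% called_keys))
  }

  # raw arm: coordinate-only deduplication
  raw_reads <- raw_duplicate_collapse(sim$reads)
  raw_pu <- build_pileup(raw_reads, sim$reference)
  raw_calls <- call_variants(raw_pu, sim$reference, threshold = threshold,
                             oxog_threshold = threshold,
                             min_depth = min_depth)

  # consensus arm: UMI adjacency grouping + filtered molecular consensus
  grouped <- group_reads_by_umi(sim$reads,
                                umi_edits = filter_params$umi_edits,
                                min_map_q = filter_params$min_map_q)
  cons <- consensus_from_families(grouped, min_reads = 1L)
  filt <- filter_consensus(cons$consensus, filter_params)
  cons_pu <- build_pileup(filt$kept, sim$reference)
  cons_calls <- call_variants(cons_pu, sim$reference,
                              threshold = threshold,
                              oxog_threshold = threshold,
                              min_depth = min_depth)
  cons_calls_oxo <- call_variants(cons_pu, sim$reference,
                                  threshold = threshold,
                                  oxog_threshold = oxog_threshold,
                                  min_depth = min_depth)
  rbindlist(list(arm_metrics(raw_calls, "raw"),
                 arm_metrics(cons_calls, "consensus"),
                 arm_metrics(cons_calls_oxo, "consensus_oxog")))
}

#' Run the full simulate-demux-consensus-call pipeline
#'
#' Simulates an experiment, writes the FASTQ set and truth table,
#' demultiplexes against the full index grid of the plate, writes the
#' cross-talk matrix, misassignment report and plate-layout counts, and --
#' when the plate carries UMIs and the config carries spike-in variants --
#' runs the raw and consensus variant-calling arms and writes their
#' variant tables and evaluation report. Identical seeds give identical
#' outputs.
#'
#' @param plate an `adapter_plate`.
#' @param sheet a `sample_sheet`.
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param max_mismatches demultiplexing mismatch tolerance (0 or 1).
#' @param threshold,oxog_threshold,min_depth variant-calling parameters.
#' @param filter_params a [consensus_filter_params()].
#' @param fastq also write the four-file FASTQ set (default TRUE).
#' @return invisibly, a list with the key in-memory objects (sim,
#'   assignments, matrix, report, and when applicable consensus and
#'   benchmark) plus `paths` of everything written.
#' @export
run_end_to_end <- function(plate, sheet, config, out_dir,
                           max_mismatches = 0L, threshold = 0.002,
                           oxog_threshold = 0.003, min_depth = 100L,
                           filter_params = consensus_filter_params(),
                           fastq = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  paths <- list()

  sim <- simulate_experiment(plate, sheet, config)
  if (fastq) {
    paths$fastq <- write_fastq(sim, p("reads"))
  }
  paths$truth <- write_truth_table(sim, p("truth.tsv"))
  paths$plate <- write_plate_layout(plate, p("plate_layout.csv"))
  paths$sheet <- write_sample_sheet(sheet, p("sample_sheet.csv"))

  policy <- demux_policy(unique(plate$wells$i7), unique(plate$wells$i5),
                         max_mismatches = max_mismatches,
                         scheme = plate$scheme)
  asg <- assign_reads(sim$reads, policy, plate, used_wells = sheet$well)
  paths$assignments <- write_assignments(asg, p("assignments.tsv"))
  mat <- build_crosstalk_matrix(asg, policy, used_wells = sheet$well)
  paths$matrix <- write_crosstalk_matrix(mat, p("crosstalk_matrix.tsv"))
  report <- misassignment_report(mat, plate)
  paths$report <- write_crosstalk_report(report, p("crosstalk_report.json"),
                                         seed = config$seed)
  paths$plate_counts <- write_plate_counts(mat, plate,
                                           p("plate_counts.tsv"))

  out <- list(sim = sim, assignments = asg, matrix = mat, report = report)

  if (plate$umi_length > 0 && !is.null(config$variants) &&
      nrow(config$variants) > 0) {
    grouped <- group_reads_by_umi(sim$reads,
                                  umi_edits = filter_params$umi_edits,
                                  min_map_q = filter_params$min_map_q)
    cons <- consensus_from_families(grouped, min_reads = 1L)
    filt <- filter_consensus(cons$consensus, filter_params)
    paths$consensus <- write_consensus_tsv(filt$kept, p("consensus.tsv"))
    cons_pu <- build_pileup(filt$kept, sim$reference)
    calls <- call_variants(cons_pu, sim$reference, threshold = threshold,
                           oxog_threshold = oxog_threshold,
                           min_depth = min_depth)
    paths$variants <- write_variant_table(calls, p("variants.tsv"))
    bench <- compare_consensus_raw(sim, threshold = threshold,
                                   oxog_threshold = oxog_threshold,
                                   min_depth = min_depth,
                                   filter_params = filter_params)
    jsonlite::write_json(bench, p("evaluation.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths$evaluation <- p("evaluation.json")
    out$consensus <- filt$kept
    out$calls <- calls
    out$benchmark <- bench
  }
  out$paths <- paths
  invisible(out)
}
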