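#' Build a per-position base pileup
#'
#' Counts A/C/G/T/N per reference position over all covering records
#' (raw reads or consensus reads). N bases are counted but excluded from
#' depth. Coordinates are 0-based half-open internally.
#'
#' @param reads data.table with columns `ref_start` (0-based) and `insert`
#'   or `bases` (record base string).
#' @param reference reference sequence string; records exceeding its bounds
#'   are an error.
#' @return a `pileup` data.table: pos (0-based), A, C, G, T, N, depth
#'   (non-N), one row per reference position.
#' @export
build_pileup <- function(reads, reference) {
  dt <- as.data.table(reads)
  col <- if ("bases" %in% names(dt)) "bases" else "insert"
  L <- nchar(reference)
  empty <- data.table(pos = seq_len(L) - 1L, A = 0L, C = 0L, G = 0L,
                      T = 0L, N = 0L, depth = 0L)
  if (nrow(dt) == 0) return(structure(empty, class = c("pileup",
                                                       class(empty))))
  if (any(dt$ref_start < 0 | dt$ref_start + nchar(dt[[col]]) > L)) {
    stop("record exceeds reference bounds")
  }
  long <- explode_reads(dt[[col]], fid = dt$ref_start)
  pos0 <- long$fid + long$pos - 1L # fid column carries ref_start here
  counts <- tabulate(pos0 * 5L + long$b, nbins = 5L * L)
  m <- matrix(counts, nrow = 5L)
  pu <- data.table(pos = seq_len(L) - 1L, A = m[1, ], C = m[2, ],
                   G = m[3, ], T = m[4, ], N = m[5, ])
  pu[, depth := A + C + G + T]
  structure(pu, class = c("pileup", class(pu)))
}

#' Call low-frequency variants from a pileup
#'
#' For every non-reference base with at least one supporting record at a
#' position with depth >= `min_depth`, the variant is called when its
#' allele fraction reaches `threshold` (default 0.2%); C>A and G>T
#' substitutions -- the 8-oxoguanine artifact class -- must instead reach
#' the mutation-specific `oxog_threshold` (default 0.3%).
#'
#' @param pileup a [build_pileup()] result.
#' @param reference reference sequence string.
#' @param threshold global allele-fraction calling threshold (default
#'   0.002).
#' @param oxog_threshold threshold for the C>A/G>T class; must be >=
#'   `threshold` (default 0.003; set equal to `threshold` to disable).
#' @param min_depth minimum depth to consider a position (default 100).
#' @return data.table with columns pos (0-based), ref, alt, alt_count,
#'   depth, af, is_oxog_class, called, filter (PASS / below_threshold /
#'   oxoG_threshold).
#' @export
call_variants <- function(pileup, reference, threshold = 0.002,
                          oxog_threshold = 0.003, min_depth = 100L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (oxog_threshold < threshold) {
    stop("oxog_threshold must be >= threshold")
  }
  ref_bases <- strsplit(reference, "")[[1]]
  pu <- as.data.table(pileup)
  rows <- lapply(DNA_BASES, function(b) {
    cnt <- pu[[b]]
    keep <- cnt >= 1L & pu$depth >= min_depth &
      ref_bases[pu$pos + 1L] != b
    if (!any(keep)) return(NULL)
    data.table(pos = pu$pos[keep], ref = ref_bases[pu$pos + 1L][keep],
               alt = b, alt_count = cnt[keep], depth = pu$depth[keep])
  })
  calls <- rbindlist(rows)
  if (nrow(calls) == 0) {
    return(data.table(pos = integer(0), ref = character(0),
                      alt = character(0), alt_count = integer(0),
                      depth = integer(0), af = numeric(0),
                      is_oxog_class = logical(0), called = logical(0),
                      filter = character(0)))
  }
  setorder(calls, pos, alt)
  calls[, af := alt_count / depth]
  calls[, is_oxog_class := (ref == "C" & alt == "A") |
          (ref == "G" & alt == "T")]
  eff_thr <- ifelse(calls$is_oxog_class, oxog_threshold, threshold)
  calls[, called := af >= eff_thr]
  calls[, filter := ifelse(called, "PASS",
                           ifelse(af >= threshold & is_oxog_class,
                                  "oxoG_threshold", "below_threshold"))]
  calls[]
}

#' Evaluate variant calls against simulation truth
#'
#' Matches calls to truth by exact (position, alt). TP = called and in
#' truth; FP = called and not in truth; FN = truth and not called.
#' Truth-based metrics are stratified by the expected allele fraction;
#' false positives are stratified by their observed allele fraction. PPV
#' with zero calls in a stratum is NA, not 0.
#'
#' @param calls a [call_variants()] result (only rows with `called = TRUE`
#'   count as calls).
#' @param truth data.frame with columns `pos` (0-based), `alt`, `af`
#'   (expected allele fraction).
#' @param strata_breaks AF bin edges (default bins at 0.75% and 1.5%,
#'   separating 0.5% and 1% spike-ins from common variants).
#' @param strata_labels bin labels.
#' @return an `eval_report` data.table: one row per stratum plus "overall",
#'   with tp, fp, fn, sensitivity, ppv.
#' @export
evaluate_calls <- function(calls, truth,
                           strata_breaks = c(0, 0.0075, 0.015, 1),
                           strata_labels = c("0.5%", "1%", ">1%")) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  called <- calls[calls$called == TRUE]
  key_call <- paste(called$pos, called$alt)
  key_truth <- paste(truth$pos, truth$alt)
  tp_mask_truth <- key_truth %in% key_call
  fp_mask_call <- !(key_call %in% key_truth)
  bin <- function(af) cut(af, breaks = strata_breaks,
                          labels = strata_labels, include.lowest = TRUE)
  truth_bin <- bin(truth$af)
  fp_bin <- bin(called$af[fp_mask_call])
  mk_row <- function(label, tp, fp, fn) {
    data.table(stratum = label, tp = tp, fp = fp, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else
                 NA_real_,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }
  rows <- lapply(strata_labels, function(lb) {
    tt <- truth_bin == lb
    mk_row(lb, sum(tp_mask_truth & tt), sum(fp_bin == lb, na.rm = TRUE),
           sum(!tp_mask_truth & tt))
  })
  rows <- c(rows, list(mk_row("overall", sum(tp_mask_truth),
                              sum(fp_mask_call),
                              sum(!tp_mask_truth))))
  out <- rbindlist(rows)
  structure(out, class = c("eval_report", class(out)))
}

#' Write a variant table as TSV
#'
#' Columns: CHROM, POS (1-based at this output boundary), REF, ALT, DP,
#' AD, AF, FILTER.
#'
#' @param calls a [call_variants()] result.
#' @param path file path.
#' @param chrom contig name (default "ref").
#' @return `path` invisibly.
#' @export
write_variant_table <- function(calls, path, chrom = "ref") {
  out <- data.frame(CHROM = chrom, POS = calls$pos + 1L, REF = calls$ref,
                    ALT = calls$alt, DP = calls$depth,
                    AD = calls$alt_count, AF = signif(calls$af, 6),
                    FILTER = calls$filter)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
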