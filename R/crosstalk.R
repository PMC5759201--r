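# map every matrix cell to the plate well carrying that (i7, i5) pair;
# cells without a plate well (e.g. off-diagonal dual-matched combinations)
# get NA
cell_wells <- function(mat, plate) {
  pair_key <- paste(plate$wells$i7, plate$wells$i5)
  grid_i7 <- rep(mat$i7_labels, times = length(mat$i5_labels))
  grid_i5 <- rep(mat$i5_labels, each = length(mat$i7_labels))
  matrix(plate$wells$well[match(paste(grid_i7, grid_i5), pair_key)],
         nrow = length(mat$i7_labels))
}

#' Misassignment report from a cross-talk matrix
#'
#' Reads demultiplexed with an index combination that was not used in
#' library preparation are evidence of cross-talk. For a combinatorial
#' plate these are reads landing in unused wells; for a unique dual-matched
#' plate, any off-diagonal (mismatched i7/i5) combination or unused
#' diagonal index. The denominator is the matrix total, i.e. reads with
#' both indices matched.
#'
#' @param mat a `crosstalk_matrix`.
#' @param plate the `adapter_plate` the matrix labels come from.
#' @param used_wells wells used in library prep; defaults to the matrix's
#'   stored `used_wells`.
#' @return a `crosstalk_report`: list with total_reads, misassigned_reads,
#'   overall_rate, per_unused_index (named counts of misassigned reads per
#'   unused well or off-plate combination), and cell metadata reused by
#'   [row_column_decomposition()].
#' @export
misassignment_report <- function(mat, plate, used_wells = mat$used_wells) {
  if (is.null(used_wells)) stop("used_wells required")
  wells <- cell_wells(mat, plate)
  total <- sum(mat$counts)
  mis_cell <- is.na(wells) | !(wells %in% used_wells)
  mis_reads <- sum(mat$counts[mis_cell])
  labels <- ifelse(is.na(wells),
                   paste0(rep(mat$i7_labels, times = ncol(mat$counts)), "/",
                          rep(mat$i5_labels, each = nrow(mat$counts))),
                   wells)
  nz <- mis_cell & mat$counts > 0
  per_unused <- tapply(mat$counts[nz], labels[nz], sum)
  per_unused <- if (is.null(per_unused)) integer(0) else
    setNames(as.integer(per_unused), names(per_unused))
  structure(list(
    total_reads = total, misassigned_reads = mis_reads,
    overall_rate = if (total > 0) mis_reads / total else 0,
    per_unused_index = per_unused,
    used_wells = used_wells, cell_well = wells, counts = mat$counts,
    scheme = mat$scheme
  ), class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat(sprintf(
    "<crosstalk_report> %d / %d reads misassigned (%.4g%%)\n",
    x$misassigned_reads, x$total_reads, 100 * x$overall_rate))
  invisible(x)
}

#' Row/column decomposition of combinatorial misassignment
#'
#' Classifies every misassigned read by the plate geometry of the unused
#' well it resolved to: whether that well shares a row (i5) and/or a column
#' (i7) with any used well. Adapter cross-contamination of a single arm
#' puts misassigned reads in the same row or column as a used well, while
#' double events are required to reach "neither" wells -- the signature
#' reported for combinatorial plates.
#'
#' @param report a `crosstalk_report` from a combinatorial experiment.
#' @param plate the `adapter_plate`.
#' @return named integer vector with elements `row_only`, `column_only`,
#'   `both`, `neither`, summing to `misassigned_reads`.
#' @export
row_column_decomposition <- function(report, plate) {
  if (report$scheme != "unique_dual" && report$scheme != "combinatorial") {
    stop("unknown scheme")
  }
  if (report$scheme == "unique_dual") {
    stop("row/column decomposition applies to combinatorial plates only")
  }
  used_idx <- plate_well_index(plate, report$used_wells)
  used_rows <- unique(plate$wells$row[used_idx])
  used_cols <- unique(plate$wells$column[used_idx])
  wells <- report$cell_well
  counts <- report$counts
  out <- c(row_only = 0L, column_only = 0L, both = 0L, neither = 0L)
  mis <- which(!is.na(wells) & !(wells %in% report$used_wells) & counts > 0)
  for (k in mis) {
    wi <- plate_well_index(plate, wells[k])
    sr <- plate$wells$row[wi] %in% used_rows
    sc <- plate$wells$column[wi] %in% used_cols
    cat_ <- if (sr && sc) "both" else if (sr) "row_only" else
      if (sc) "column_only" else "neither"
    out[cat_] <- out[cat_] + counts[k]
  }
  out
}

#' Fraction of reads with mismatched i7/i5 index pairs
#'
#' For unique dual-matched libraries a read whose matched i7 and i5 labels
#' differ cannot be a legitimate library molecule; the off-diagonal mass of
#' the all-combinations matrix over its total is the paper-style
#' contamination / hopping readout.
#'
#' @param mat a square `crosstalk_matrix` with identical i7 and i5 labels.
#' @return fraction in [0, 1].
#' @export
mismatched_pair_rate <- function(mat) {
  if (!identical(mat$i7_labels, mat$i5_labels)) {
    stop("mismatched_pair_rate requires identical i7 and i5 label sets")
  }
  total <- sum(mat$counts)
  if (total == 0) return(0)
  sum(mat$counts[row(mat$counts) != col(mat$counts)]) / total
}

#' Baseline-corrected index-hopping estimates
#'
#' Single-plex captures cannot hop (there is no other library to exchange
#' indices with), so their mismatched-pair rate measures pure adapter
#' contamination. Subtracting that baseline from each multiplexed pool's
#' mismatched-pair rate (floored at zero) isolates hopping. Since each of
#' the two indices hops independently at some per-index rate h, the
#' mismatched-read rate is approximately 1 - (1 - h)^2; the implied
#' per-index rate reported alongside inverts that.
#'
#' @param pool_matrices named list of `crosstalk_matrix` objects, one per
#'   multiplexed pool (names identify the pools, e.g. plex size).
#' @param singleplex_matrix the single-plex baseline matrix, or NULL (then
#'   estimates are uncorrected and flagged).
#' @return data.frame with one row per pool: pool, plex_size,
#'   mismatched_pair_rate, baseline_rate, corrected_hop_rate,
#'   implied_per_index_rate, corrected.
#' @export
hop_rate_estimate <- function(pool_matrices, singleplex_matrix = NULL) {
  if (is.null(singleplex_matrix)) {
    baseline <- 0
    corrected <- FALSE
    warning("no single-plex baseline: estimates are uncorrected")
  } else {
    baseline <- mismatched_pair_rate(singleplex_matrix)
    corrected <- TRUE
  }
  nm <- names(pool_matrices)
  if (is.null(nm)) nm <- as.character(seq_along(pool_matrices))
  rows <- lapply(seq_along(pool_matrices), function(i) {
    m <- pool_matrices[[i]]
    r <- mismatched_pair_rate(m)
    ch <- max(0, r - baseline)
    data.frame(pool = nm[i],
               plex_size = if (!is.null(m$used_wells))
                 length(m$used_wells) else NA_integer_,
               mismatched_pair_rate = r, baseline_rate = baseline,
               corrected_hop_rate = ch,
               implied_per_index_rate = 1 - sqrt(max(0, 1 - ch)),
               corrected = corrected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diagnose the contamination stage from matrix symmetry
#'
#' Contamination of duplexed adapters contributes both arms of the
#' contaminant, so cell (X, S) and cell (S, X) fill at the same rate and
#' the off-diagonal pattern is symmetric. Contamination of single-stranded
#' oligos leaks only one arm, filling one of the two cells -- a skewed
#' pattern. The score is
#' sum |off(i,j) - off(j,i)| / sum (off(i,j) + off(j,i)) over off-diagonal
#' pairs: 0 for perfect symmetry, 1 for complete skew.
#'
#' @param mat a square `crosstalk_matrix`.
#' @param skew_threshold verdict "skewed" when score exceeds this and at
#'   least `min_offdiag` off-diagonal reads exist (default 0.5).
#' @param symmetric_threshold verdict "symmetric" below this (default 0.2).
#' @param min_offdiag minimum off-diagonal reads for a confident skew call
#'   (default 50).
#' @return list with `asymmetry_score`, `verdict` ("skewed", "symmetric" or
#'   "indeterminate") and `off_diagonal_reads`.
#' @export
symmetry_diagnostic <- function(mat, skew_threshold = 0.5,
                                symmetric_threshold = 0.2,
                                min_offdiag = 50L) {
  m <- mat$counts
  if (nrow(m) != ncol(m)) stop("square matrix required")
  ut <- upper.tri(m)
  a <- m[ut]
  b <- t(m)[ut]
  keep <- (a + b) > 0
  off_total <- sum(a) + sum(b)
  if (!any(keep)) {
    return(list(asymmetry_score = NA_real_, verdict = "indeterminate",
                off_diagonal_reads = 0L))
  }
  score <- sum(abs(a[keep] - b[keep])) / sum(a[keep] + b[keep])
  verdict <- if (score > skew_threshold && off_total >= min_offdiag) {
    "skewed"
  } else if (score < symmetric_threshold) {
    "symmetric"
  } else {
    "indeterminate"
  }
  list(asymmetry_score = score, verdict = verdict,
       off_diagonal_reads = off_total)
}

#' Analytic contamination-to-misassignment model
#'
#' With a contamination fraction c of a foreign adapter in a sample's pool:
#' under single-index discrimination every contaminated fragment is
#' misassigned, giving a misassigned fraction of c. Under the unique
#' dual-matched scheme the two adapter arms are drawn independently, so
#' both indices are foreign with probability c^2 (misassigned), while
#' exactly one arm is foreign with probability 2c(1 - c) -- those reads
#' carry mismatched indices and are filtered, not misassigned.
#'
#' @param c contamination fraction in [0, 1].
#' @param mode "single_index" or "dual_matched".
#' @return named numeric vector `c(misassigned = , filtered = )`.
#' @export
expected_misassignment <- function(c, mode = c("single_index",
                                               "dual_matched")) {
  mode <- match.arg(mode)
  if (c < 0 || c > 1) stop("c must be in [0, 1]")
  if (mode == "single_index") {
    c(misassigned = c, filtered = 0)
  } else {
    c(misassigned = c^2, filtered = 2 * c * (1 - c))
  }
}

#' Write a misassignment report as JSON
#'
#' @param report a `crosstalk_report`.
#' @param path file path.
#' @param seed optional seed to record.
#' @return `path` invisibly.
#' @export
write_crosstalk_report <- function(report, path, seed = NULL) {
  out <- list(total_reads = report$total_reads,
              misassigned_reads = report$misassigned_reads,
              overall_rate = report$overall_rate,
              per_unused_index = as.list(report$per_unused_index),
              used_wells = report$used_wells, scheme = report$scheme)
  if (!is.null(seed)) out$seed <- seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-well read counts in 96-well plate layout
#'
#' Mirrors the figure-style plate view: one TSV row per plate row (A-H),
#' one column per plate column (1-12), each cell the number of reads
#' demultiplexed to that well.
#'
#' @param mat a `crosstalk_matrix`.
#' @param plate the `adapter_plate`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_plate_counts <- function(mat, plate, path) {
  wells <- cell_wells(mat, plate)
  per_well <- tapply(mat$counts[!is.na(wells)], wells[!is.na(wells)], sum)
  grid <- matrix(0L, plate$n_rows, plate$n_cols,
                 dimnames = list(LETTERS[seq_len(plate$n_rows)],
                                 seq_len(plate$n_cols)))
  wi <- plate_well_index(plate, names(per_well))
  grid[cbind(match(plate$wells$row[wi], rownames(grid)),
             plate$wells$column[wi])] <- as.integer(per_well)
  df <- data.frame(row = rownames(grid), grid, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
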