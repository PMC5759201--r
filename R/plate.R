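#' @importFrom stats runif rbinom rpois rgeom setNames
#' @importFrom utils read.csv write.csv adist
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Validate a set of index sequences
#'
#' Index sequences are fixed-length barcodes over the DNA alphabet, read as
#' dedicated index reads (i7 and i5) on Illumina-style instruments.
#'
#' @param x character vector of candidate index sequences.
#' @param length required sequence length (default 8, the TruSeq HT
#'   convention).
#' @return `x` invisibly, after validation.
#' @export
validate_index_sequences <- function(x, length = 8L) {
  if (!is.character(x) || length(x) == 0) {
    stop("index sequences must be a non-empty character vector")
  }
  if (any(nchar(x) != length)) {
    stop("all index sequences must have length ", length)
  }
  if (any(grepl("[^ACGT]", x))) {
    stop("index sequences must use only A/C/G/T")
  }
  invisible(x)
}

well_id <- function(row, column) paste0(row, column)

new_adapter_plate <- function(scheme, wells, umi_length, n_rows, n_cols) {
  structure(
    list(scheme = scheme, wells = wells, umi_length = as.integer(umi_length),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "adapter_plate"
  )
}

#' @export
print.adapter_plate <- function(x, ...) {
  cat(sprintf("<adapter_plate> scheme=%s wells=%d (%dx%d) umi_length=%d\n",
              x$scheme, nrow(x$wells), x$n_rows, x$n_cols, x$umi_length))
  invisible(x)
}

#' Build a combinatorial adapter plate
#'
#' The combinatorial (TruSeq HT style) design derives 96 sample identities
#' from only 20 oligos: 12 i7 indices, one per plate column, and 8 i5
#' indices, one per plate row. Every well in a column shares its i7 and
#' every well in a row shares its i5, so single indices are shared across
#' samples.
#'
#' @param i7_list character vector of i7 index sequences, one per column.
#' @param i5_list character vector of i5 index sequences, one per row.
#' @param index_length index length; all sequences must match.
#' @return an `adapter_plate` object with `length(i7_list) * length(i5_list)`
#'   wells, each carrying a distinct (i7, i5) pair, and `umi_length = 0`.
#' @examples
#' set.seed(1)
#' idx <- design_index_set(20)
#' plate <- make_combinatorial_plate(idx[1:12], idx[13:20])
#' @export
make_combinatorial_plate <- function(i7_list, i5_list, index_length = 8L) {
  validate_index_sequences(i7_list, index_length)
  validate_index_sequences(i5_list, index_length)
  if (anyDuplicated(i7_list)) stop("duplicate sequences in i7_list")
  if (anyDuplicated(i5_list)) stop("duplicate sequences in i5_list")
  if (length(intersect(i7_list, i5_list)) > 0) {
    stop("i7_list and i5_list share sequences")
  }
  n_cols <- length(i7_list)
  n_rows <- length(i5_list)
  if (n_rows > 26) stop("at most 26 rows supported")
  rows <- LETTERS[seq_len(n_rows)]
  grid <- expand.grid(row = rows, column = seq_len(n_cols),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wells <- data.frame(
    well = well_id(grid$row, grid$column),
    row = grid$row,
    column = as.integer(grid$column),
    i7 = i7_list[grid$column],
    i5 = i5_list[match(grid$row, rows)],
    stringsAsFactors = FALSE
  )
  wells <- wells[order(match(wells$row, LETTERS), wells$column), ]
  rownames(wells) <- NULL
  new_adapter_plate("combinatorial", wells, 0L, n_rows, n_cols)
}

#' Build a unique dual-matched adapter plate
#'
#' Each well receives its own adapter whose i5 and i7 indices are the
#' identical sequence, shared with no other well, plus a short UMI appended
#' 3' of the i7 index. A read whose observed i7 and i5 disagree can only
#' arise from a cross-talk event and is excluded at demultiplexing.
#'
#' Wells are filled row-major from A1 when fewer than `n_rows * n_cols`
#' indices are supplied.
#'
#' @param indices character vector of distinct index sequences, one per well.
#' @param umi_length UMI length in nucleotides appended to the i7 read
#'   (default 6).
#' @param n_rows,n_cols plate bounds (default 8 x 12).
#' @param index_length index length.
#' @return an `adapter_plate` with `length(indices)` wells, `i7 == i5`
#'   within each well.
#' @export
make_unique_dual_plate <- function(indices, umi_length = 6L, n_rows = 8L,
                                   n_cols = 12L, index_length = 8L) {
  validate_index_sequences(indices, index_length)
  if (anyDuplicated(indices)) stop("duplicate index sequences")
  n <- length(indices)
  if (n > n_rows * n_cols) stop("more indices than wells on the plate")
  if (umi_length < 0) stop("umi_length must be >= 0")
  k <- seq_len(n) - 1L
  rows <- LETTERS[k %/% n_cols + 1L]
  cols <- as.integer(k %% n_cols + 1L)
  wells <- data.frame(
    well = well_id(rows, cols), row = rows, column = cols,
    i7 = indices, i5 = indices, stringsAsFactors = FALSE
  )
  new_adapter_plate("unique_dual", wells, umi_length, n_rows, n_cols)
}

#' Minimum pairwise edit distance of a plate's index sequences
#'
#' Robust index designs keep all indices at Levenshtein distance >= 3 so
#' that substitution, insertion and deletion errors cannot convert one index
#' into another.
#'
#' @param plate an `adapter_plate`, or a character vector of sequences.
#' @return the minimum Levenshtein distance over all unordered pairs of
#'   distinct index sequences.
#' @export
min_pairwise_edit_distance <- function(plate) {
  seqs <- if (inherits(plate, "adapter_plate")) {
    unique(c(plate$wells$i7, plate$wells$i5))
  } else {
    unique(as.character(plate))
  }
  if (length(seqs) < 2) stop("need at least 2 distinct index sequences")
  d <- adist(seqs)
  min(d[upper.tri(d)])
}

#' GC fraction of a sequence
#'
#' @param x character vector of sequences.
#' @return numeric vector of (G + C) / length values in [0, 1].
#' @export
gc_fraction <- function(x) {
  if (any(nchar(x) == 0)) stop("empty sequence")
  gc <- nchar(gsub("[^GC]", "", x))
  gc / nchar(x)
}

#' Generate an index set satisfying design constraints
#'
#' Draws random fixed-length sequences with the requested GC content and
#' greedily retains those at or above the minimum pairwise Levenshtein
#' distance from all previously accepted sequences. Mirrors the constraints
#' of commercial unique dual-index designs (edit distance >= 3, 50% GC).
#' Uses the session RNG; call `set.seed()` for reproducibility.
#'
#' @param n number of sequences to generate.
#' @param length sequence length (default 8).
#' @param min_edit_dist minimum pairwise Levenshtein distance (default 3).
#' @param gc_content target GC fraction; the GC base count is
#'   `round(gc_content * length)` exactly (default 0.5).
#' @param max_tries candidate draws before giving up.
#' @return character vector of `n` index sequences.
#' @export
design_index_set <- function(n, length = 8L, min_edit_dist = 3L,
                             gc_content = 0.5, max_tries = 10000L) {
  n_gc <- round(gc_content * length)
  accepted <- character(0)
  tries <- 0L
  while (length(accepted) < n && tries < max_tries) {
    tries <- tries + 1L
    pos_gc <- sample.int(length, n_gc)
    bases <- character(length)
    bases[pos_gc] <- sample(c("G", "C"), n_gc, replace = TRUE)
    bases[-pos_gc] <- sample(c("A", "T"), length - n_gc, replace = TRUE)
    cand <- paste(bases, collapse = "")
    if (length(accepted) == 0 ||
        min(adist(cand, accepted)) >= min_edit_dist) {
      accepted <- c(accepted, cand)
    }
  }
  if (length(accepted) < n) {
    stop("could not generate ", n, " indices in ", max_tries, " tries")
  }
  accepted
}

#' Create a sample sheet
#'
#' @param sample_id character vector of unique sample names.
#' @param well character vector of well ids (e.g. "A1") on the plate.
#' @param plate optional `adapter_plate` to validate wells against.
#' @return a `sample_sheet` data.frame with columns sample_id, well, row,
#'   column.
#' @export
sample_sheet <- function(sample_id, well, plate = NULL) {
  if (length(sample_id) != length(well)) {
    stop("sample_id and well must have the same length")
  }
  if (anyDuplicated(sample_id)) stop("duplicate sample_id")
  if (anyDuplicated(well)) stop("duplicate well")
  row <- sub("^([A-Z]).*$", "\\1", well)
  column <- as.integer(sub("^[A-Z]", "", well))
  sheet <- data.frame(sample_id = as.character(sample_id),
                      well = as.character(well),
                      row = row, column = column, stringsAsFactors = FALSE)
  class(sheet) <- c("sample_sheet", "data.frame")
  if (!is.null(plate)) validate_sample_sheet(sheet, plate)
  sheet
}

validate_sample_sheet <- function(sheet, plate) {
  bad <- setdiff(sheet$well, plate$wells$well)
  if (length(bad) > 0) {
    stop("sample sheet references wells not on the plate: ",
         paste(bad, collapse = ", "))
  }
  invisible(sheet)
}

#' Read / write a sample sheet CSV
#'
#' The on-disk format is a comma-delimited UTF-8 file with header
#' `sample_id,row,column`.
#'
#' @param path file path.
#' @param plate optional `adapter_plate` for validation on load.
#' @return `read_sample_sheet` returns a `sample_sheet`;
#'   `write_sample_sheet` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path, plate = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "row", "column")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have header sample_id,row,column")
  }
  if (nrow(df) == 0) {
    return(sample_sheet(character(0), character(0), plate))
  }
  dup <- which(duplicated(df$sample_id))
  if (length(dup) > 0) {
    stop("duplicate sample_id at line ", dup[1] + 1L)
  }
  w <- well_id(df$row, df$column)
  dupw <- which(duplicated(w))
  if (length(dupw) > 0) stop("duplicate well at line ", dupw[1] + 1L)
  if (!is.null(plate)) {
    bad <- which(!(w %in% plate$wells$well))
    if (length(bad) > 0) {
      stop("unknown well '", w[bad[1]], "' at line ", bad[1] + 1L)
    }
  }
  sample_sheet(df$sample_id, w, plate)
}

#' @param sheet a `sample_sheet`.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(sheet[, c("sample_id", "row", "column")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a plate layout CSV
#'
#' Format: a comment line `#scheme=<scheme>,umi_length=<n>,n_rows=<r>,
#' n_cols=<c>` followed by a comma-delimited table with header
#' `row,column,i7,i5`.
#'
#' @param plate an `adapter_plate`.
#' @param path file path.
#' @return `read_plate_layout` returns an `adapter_plate`;
#'   `write_plate_layout` returns `path` invisibly.
#' @export
write_plate_layout <- function(plate, path) {
  hdr <- sprintf("#scheme=%s,umi_length=%d,n_rows=%d,n_cols=%d",
                 plate$scheme, plate$umi_length, plate$n_rows, plate$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(plate$wells[, c("row", "column", "i7", "i5")], con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#scheme=", lines[1])) stop("missing plate scheme header line")
  kv <- strsplit(sub("^#", "", lines[1]), ",")[[1]]
  meta <- setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  df <- read.csv(text = lines[-1], stringsAsFactors = FALSE)
  wells <- data.frame(
    well = well_id(df$row, df$column), row = df$row,
    column = as.integer(df$column), i7 = df$i7, i5 = df$i5,
    stringsAsFactors = FALSE
  )
  plate <- new_adapter_plate(meta[["scheme"]], wells,
                             as.integer(meta[["umi_length"]]),
                             as.integer(meta[["n_rows"]]),
                             as.integer(meta[["n_cols"]]))
  validate_plate(plate)
  plate
}

validate_plate <- function(plate) {
  w <- plate$wells
  if (anyDuplicated(w$well)) stop("duplicate wells")
  if (anyDuplicated(paste(w$i7, w$i5))) stop("duplicate (i7, i5) pairs")
  if (plate$scheme == "unique_dual") {
    if (!all(w$i7 == w$i5)) stop("unique_dual plate requires i7 == i5")
    if (anyDuplicated(w$i7)) stop("unique_dual index used in multiple wells")
  } else if (plate$scheme == "combinatorial") {
    by_col <- split(w$i7, w$column)
    by_row <- split(w$i5, w$row)
    if (any(vapply(by_col, function(x) length(unique(x)), 1L) != 1L)) {
      stop("combinatorial plate: wells in a column must share i7")
    }
    if (any(vapply(by_row, function(x) length(unique(x)), 1L) != 1L)) {
      stop("combinatorial plate: wells in a row must share i5")
    }
  } else {
    stop("unknown scheme: ", plate$scheme)
  }
  invisible(plate)
}

plate_well_index <- function(plate, wells) {
  i <- match(wells, plate$wells$well)
  if (anyNA(i)) stop("unknown well: ", wells[which(is.na(i))[1]])
  i
}
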