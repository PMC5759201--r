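# Pairwise Hamming distances for equal-length sequences (small sets)
hamming_pairwise <- function(seqs) {
  K <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0L, K, K)
  for (i in seq_len(K - 1)) {
    for (j in seq((i + 1), K)) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

# lookup table string -> candidate index for Hamming distance <= max_mm;
# ambiguous strings (>= 2 candidates at the same minimal distance) map to NA
build_index_lookup <- function(candidates, max_mm) {
  L <- nchar(candidates[1])
  K <- length(candidates)
  entries <- data.table(seq = candidates, cand = seq_len(K), dist = 0L)
  if (max_mm >= 1) {
    neigh <- vector("list", L)
    for (p in seq_len(L)) {
      cur <- substr(candidates, p, p)
      for (b in DNA_BASES) {
        alt <- candidates[cur != b]
        ci <- which(cur != b)
        if (length(alt) == 0) next
        s <- alt
        substr(s, p, p) <- b
        neigh[[p]] <- rbind(neigh[[p]],
                            data.table(seq = s, cand = ci, dist = 1L))
      }
    }
    entries <- rbind(entries, rbindlist(neigh))
  }
  dist <- cand <- ambiguous <- NULL # data.table NSE columns
  ent <- entries[order(seq, dist)]
  res <- ent[, {
    dmin <- dist[1]
    at_min <- cand[dist == dmin]
    list(cand = if (length(unique(at_min)) == 1L) at_min[1] else NA_integer_,
         dist = dmin,
         ambiguous = length(unique(at_min)) > 1L)
  }, by = seq]
  res
}

#' Match an observed index against a candidate set
#'
#' Returns, per observed sequence, the unique candidate within Hamming
#' distance `max_mismatches`; no candidate qualifies, or two or more
#' candidates tie at the minimal qualifying distance (ambiguity), yields no
#' match. N or other non-ACGT characters count as mismatches at their
#' position.
#'
#' @param observed character vector of observed index sequences.
#' @param candidates character vector of candidate index sequences, all the
#'   same length as the observed sequences.
#' @param max_mismatches 0 (perfect match) or 1.
#' @return data.frame with columns `candidate` (matched sequence or NA),
#'   `mismatches` (Hamming distance of the match, NA if none) and
#'   `ambiguous`.
#' @export
match_index <- function(observed, candidates, max_mismatches = 0L) {
  if (length(unique(nchar(candidates))) != 1) {
    stop("candidates must share one length")
  }
  if (any(nchar(observed) != nchar(candidates[1]))) {
    stop("observed and candidate index lengths differ")
  }
  if (!max_mismatches %in% c(0L, 1L)) {
    stop("max_mismatches must be 0 or 1")
  }
  if (anyDuplicated(candidates)) stop("duplicate candidates")
  if (max_mismatches == 0L) {
    i <- match(observed, candidates)
    return(data.frame(candidate = candidates[i],
                      mismatches = ifelse(is.na(i), NA_integer_, 0L),
                      ambiguous = FALSE, stringsAsFactors = FALSE))
  }
  lk <- build_index_lookup(candidates, 1L)
  j <- match(observed, lk$seq)
  data.frame(
    candidate = candidates[lk$cand[j]],
    mismatches = ifelse(is.na(j) | is.na(lk$cand[j]), NA_integer_,
                        lk$dist[j]),
    ambiguous = !is.na(j) & lk$ambiguous[j],
    stringsAsFactors = FALSE
  )
}

#' Demultiplexing policy
#'
#' Fixes the candidate index space (used and unused indices), the mismatch
#' tolerance and the adapter scheme. With `max_mismatches = 1` the minimum
#' pairwise Hamming distance of each candidate set must exceed 2 so that
#' every observed sequence has at most one candidate within tolerance; sets
#' violating this fail at construction.
#'
#' @param i7_candidates,i5_candidates candidate index sequences; for a
#'   unique dual-matched experiment these are typically identical.
#' @param max_mismatches 0 (perfect match) or 1 (one mismatch per index).
#' @param scheme "combinatorial" or "unique_dual".
#' @param use_i5 if FALSE, demultiplex on the i7 index alone (genotyping
#'   mode); i5 matching is skipped.
#' @return a `demux_policy` object.
#' @export
demux_policy <- function(i7_candidates, i5_candidates = i7_candidates,
                         max_mismatches = 0L,
                         scheme = c("unique_dual", "combinatorial"),
                         use_i5 = TRUE) {
  scheme <- match.arg(scheme)
  if (!max_mismatches %in% c(0L, 1L)) {
    stop("max_mismatches must be 0 or 1")
  }
  if (length(i7_candidates) == 0 || (use_i5 && length(i5_candidates) == 0)) {
    stop("candidate sets must be non-empty")
  }
  if (anyDuplicated(i7_candidates) || anyDuplicated(i5_candidates)) {
    stop("duplicate candidate sequences")
  }
  if (max_mismatches == 1L) {
    for (cand in list(i7 = i7_candidates, i5 = i5_candidates)) {
      if (length(cand) > 1) {
        dmin <- min(hamming_pairwise(cand)[upper.tri(diag(length(cand)))])
        if (dmin <= 2L) {
          stop("with max_mismatches = 1 the minimum pairwise Hamming ",
               "distance of each candidate set must exceed 2 (found ",
               dmin, ")")
        }
      }
    }
  }
  structure(list(i7_candidates = i7_candidates,
                 i5_candidates = i5_candidates,
                 max_mismatches = as.integer(max_mismatches),
                 scheme = scheme, use_i5 = use_i5),
            class = "demux_policy")
}

# fast candidate-index lookup; returns integer candidate indices (NA = no
# unique match)
lookup_candidates <- function(observed, candidates, max_mm) {
  if (max_mm == 0L) return(match(observed, candidates))
  lk <- build_index_lookup(candidates, max_mm)
  j <- match(observed, lk$seq)
  lk$cand[j]
}

#' Assign reads to samples or index combinations
#'
#' The i7 and i5 indices are matched independently against the policy's
#' candidate sets; a read resolves to the plate well whose (i7, i5) pair
#' equals the matched combination. Combinations absent from the plate (for
#' a unique dual-matched scheme, any i7 != i5 pair) are retained as
#' combination assignments and flagged `not_a_well`; hidden truth fields
#' never participate.
#'
#' @param reads data.frame/data.table with columns `read_id`, `i7_obs`,
#'   `i5_obs` (UMI bases already split off the i7 read).
#' @param policy a [demux_policy()].
#' @param plate an `adapter_plate`.
#' @param used_wells wells actually used in library preparation; needed to
#'   resolve wells in i7-only mode, optional otherwise.
#' @return data.table with columns read_id, i7_match, i5_match, well,
#'   mismatched_pair, not_a_well, unassigned.
#' @export
assign_reads <- function(reads, policy, plate, used_wells = NULL) {
  reads <- as.data.table(reads)
  i7i <- lookup_candidates(reads$i7_obs, policy$i7_candidates,
                           policy$max_mismatches)
  i7_match <- policy$i7_candidates[i7i]
  if (policy$use_i5) {
    i5i <- lookup_candidates(reads$i5_obs, policy$i5_candidates,
                             policy$max_mismatches)
    i5_match <- policy$i5_candidates[i5i]
    both <- !is.na(i7_match) & !is.na(i5_match)
    pair_key <- paste(plate$wells$i7, plate$wells$i5)
    well <- plate$wells$well[match(paste(i7_match, i5_match), pair_key)]
    well[!both] <- NA_character_
    mismatched_pair <- both & policy$scheme == "unique_dual" &
      i7_match != i5_match
    not_a_well <- both & is.na(well)
    unassigned <- !both
  } else {
    # i7-only (genotyping) mode: resolve among the used wells' i7 indices
    ref_wells <- if (is.null(used_wells)) plate$wells$well else used_wells
    wi <- plate_well_index(plate, ref_wells)
    i7_of_well <- plate$wells$i7[wi]
    tab <- table(i7_of_well)
    uniq <- names(tab)[tab == 1L]
    well <- ref_wells[match(i7_match, i7_of_well)]
    well[!(i7_match %in% uniq)] <- NA_character_
    i5_match <- rep(NA_character_, nrow(reads))
    mismatched_pair <- rep(FALSE, nrow(reads))
    not_a_well <- !is.na(i7_match) & is.na(well)
    unassigned <- is.na(i7_match)
  }
  data.table(read_id = reads$read_id, i7_match = i7_match,
             i5_match = i5_match, well = well,
             mismatched_pair = mismatched_pair, not_a_well = not_a_well,
             unassigned = unassigned)
}

#' Build a cross-talk matrix over the full index grid
#'
#' Counts reads per observed (i7, i5) candidate combination -- used and
#' unused indices alike, e.g. all 35 x 35 = 1225 combinations of a 35-index
#' dual-matched experiment. Only reads with both indices matched enter the
#' matrix, so the matrix total equals the number of dual-matched reads.
#'
#' @param reads read table as for [assign_reads()], or an assignment table
#'   already produced by it (detected by its columns).
#' @param policy a [demux_policy()] with `use_i5 = TRUE`.
#' @param used_wells optional character vector of wells used in library
#'   prep, stored for downstream reports.
#' @param plate optional `adapter_plate` used only when `reads` must first
#'   be assigned.
#' @return a `crosstalk_matrix`: list with `counts` (N x M integer matrix,
#'   rows = i7 candidates, columns = i5 candidates), labels, `scheme` and
#'   `used_wells`.
#' @export
build_crosstalk_matrix <- function(reads, policy, used_wells = NULL,
                                   plate = NULL) {
  stopifnot(policy$use_i5)
  if (all(c("i7_match", "i5_match") %in% names(reads))) {
    asg <- as.data.table(reads)
  } else {
    if (is.null(plate)) stop("plate required to assign raw reads")
    asg <- assign_reads(reads, policy, plate)
  }
  keep <- !is.na(asg$i7_match) & !is.na(asg$i5_match)
  i7f <- factor(asg$i7_match[keep], levels = policy$i7_candidates)
  i5f <- factor(asg$i5_match[keep], levels = policy$i5_candidates)
  counts <- table(i7f, i5f)
  counts <- matrix(as.integer(counts), nrow = length(policy$i7_candidates),
                   dimnames = list(i7 = policy$i7_candidates,
                                   i5 = policy$i5_candidates))
  structure(list(counts = counts, i7_labels = policy$i7_candidates,
                 i5_labels = policy$i5_candidates, scheme = policy$scheme,
                 used_wells = used_wells),
            class = "crosstalk_matrix")
}

#' @export
print.crosstalk_matrix <- function(x, ...) {
  cat(sprintf("<crosstalk_matrix> %d x %d combinations, %d reads, scheme=%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$scheme))
  invisible(x)
}

#' Write / read a cross-talk matrix TSV
#'
#' Rows are i7 candidates, columns i5 candidates, cells integer read
#' counts.
#'
#' @param mat a `crosstalk_matrix`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_crosstalk_matrix <- function(mat, path) {
  df <- data.frame(i7 = rownames(mat$counts), mat$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-read assignments as TSV
#'
#' @param assignments output of [assign_reads()].
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_assignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
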