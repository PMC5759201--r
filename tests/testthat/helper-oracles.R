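# Independent oracles and small fixtures used across the suite.

suppressMessages(library(data.table))

# textbook dynamic-programming Levenshtein distance
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force nearest-candidate index matching: unique candidate at the
# minimal qualifying Hamming distance, else NA
bf_match <- function(observed, candidates, max_mm) {
  vapply(observed, function(o) {
    d <- vapply(candidates, hamming_str, 0L, a = o)
    dmin <- min(d)
    if (dmin > max_mm) return(NA_character_)
    hits <- candidates[d == dmin]
    if (length(hits) == 1L) hits else NA_character_
  }, "", USE.NAMES = FALSE)
}

# brute-force adjacency clustering of read UMIs: repeated-closure
# formulation of the directed count-ratio rule, independent of the
# package's breadth-first implementation
bf_adjacency <- function(umis, edits = 1L) {
  tab <- table(umis)
  nm <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, nm)
  nm <- nm[ord]
  cnt <- cnt[ord]
  K <- length(nm)
  fam <- rep(NA_integer_, K)
  fid <- 0L
  for (i in seq_len(K)) {
    if (!is.na(fam[i])) next
    fid <- fid + 1L
    fam[i] <- fid
    repeat {
      added <- FALSE
      for (j in seq_len(K)) {
        if (!is.na(fam[j])) next
        for (k in seq_len(K)) {
          if (is.na(fam[k]) || fam[k] != fid) next
          if (hamming_str(nm[k], nm[j]) <= edits &&
              cnt[k] >= 2L * cnt[j] - 1L) {
            fam[j] <- fid
            added <- TRUE
            break
          }
        }
      }
      if (!added) break
    }
  }
  fam[match(umis, nm)]
}

# canonical relabelling of a partition vector so two partitions can be
# compared independent of label values
canon_partition <- function(f) {
  match(f, unique(f))
}

# deterministic small plates shared across tests
fixture_dual_plate <- function(n = 4, umi_length = 6, seed = 101) {
  set.seed(seed)
  make_unique_dual_plate(design_index_set(n), umi_length = umi_length)
}

fixture_comb_plate <- function(seed = 202) {
  set.seed(seed)
  idx <- design_index_set(20)
  make_combinatorial_plate(idx[1:12], idx[13:20])
}

# hand-built crosstalk matrix object for unit tests
manual_matrix <- function(counts, labels_i7 = rownames(counts),
                          labels_i5 = colnames(counts),
                          scheme = "unique_dual", used_wells = NULL) {
  dimnames(counts) <- list(i7 = labels_i7, i5 = labels_i5)
  structure(list(counts = counts, i7_labels = labels_i7,
                 i5_labels = labels_i5, scheme = scheme,
                 used_wells = used_wells),
            class = "crosstalk_matrix")
}
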