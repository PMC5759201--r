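BASE5 <- c("A", "C", "G", "T", "N")

# explode equal-or-variable-length base strings into a long table
# (fid, pos, base index 1..5, qual). Uses one raw-byte pass, so it scales
# to millions of bases.
explode_reads <- function(bases, fid = seq_along(bases), quals = NULL) {
  lens <- nchar(bases)
  raw <- charToRaw(paste(bases, collapse = ""))
  code <- integer(256)
  code[as.integer(charToRaw(paste(BASE5, collapse = ""))) + 1L] <-
    seq_len(5L)
  b <- code[as.integer(raw) + 1L]
  if (any(b == 0L)) stop("bases must be over A/C/G/T/N")
  out <- data.table(fid = rep(fid, lens), pos = sequence(lens), b = b)
  if (!is.null(quals)) {
    qraw <- charToRaw(paste(quals, collapse = ""))
    out[, qual := as.integer(qraw) - 33L]
  }
  out
}

# adjacency clustering of one positional bucket's distinct UMIs.
# `umis` must be sorted by decreasing count, ties broken lexicographically.
# Directed edge A -> B exists when Hamming(A, B) <= edits and
# count(A) >= 2 * count(B) - 1; families grow breadth-first from the
# highest-count unassigned root through such edges.
adjacency_families <- function(umis, counts, edits = 1L) {
  K <- length(umis)
  if (K == 1L) return(1L)
  d <- hamming_pairwise(umis)
  fam <- integer(K)
  next_fam <- 0L
  for (r in seq_len(K)) {
    if (fam[r] != 0L) next
    next_fam <- next_fam + 1L
    fam[r] <- next_fam
    frontier <- r
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- which(fam == 0L & d[f, ] <= edits &
                      counts[f] >= 2L * counts - 1L)
        if (length(nb) > 0) {
          fam[nb] <- next_fam
          nxt <- c(nxt, nb)
        }
      }
      frontier <- nxt
    }
  }
  fam
}

#' Group reads into molecular families by position and UMI
#'
#' Reads below `min_map_q` are excluded. Within each (ref_start, strand)
#' bucket, distinct UMIs form a directed adjacency network: an edge runs
#' from UMI A to UMI B when their Hamming distance is at most `umi_edits`
#' and count(A) >= 2 * count(B) - 1, the count-ratio rule that merges
#' sequencing-error variants of a true UMI without chaining independent
#' molecules. Families are grown breadth-first from the highest-count
#' unassigned UMI; the canonical UMI of a family is its highest-count
#' member.
#'
#' @param reads data.frame/data.table with columns `read_id`, `ref_start`,
#'   `strand`, `umi` (or `umi_obs`) and optionally `mapq`; other columns
#'   (e.g. insert bases) are carried through.
#' @param umi_edits maximum Hamming distance for adjacency (default 1).
#' @param min_map_q minimum mapping quality (default 10).
#' @return a data.table of the retained reads with added columns
#'   `family_id`, `canonical_umi` and `family_size` (reads in the family).
#' @export
group_reads_by_umi <- function(reads, umi_edits = 1L, min_map_q = 10L) {
  dt <- as.data.table(reads)
  if (!"umi" %in% names(dt)) {
    if ("umi_obs" %in% names(dt)) dt[, umi := umi_obs] else
      stop("reads need a 'umi' or 'umi_obs' column")
  }
  if ("mapq" %in% names(dt)) dt <- dt[dt$mapq >= min_map_q]
  if (nrow(dt) == 0) {
    dt[, `:=`(family_id = integer(0), canonical_umi = character(0),
              family_size = integer(0))]
    return(dt)
  }
  if (length(unique(nchar(dt$umi))) != 1) stop("UMI length inconsistency")
  N <- fam_local <- family_id <- canonical_umi <- family_size <- NULL
  umap <- dt[, .N, by = c("ref_start", "strand", "umi")]
  setorder(umap, ref_start, strand, -N, umi)
  umap[, fam_local := adjacency_families(umi, N, as.integer(umi_edits)),
       by = c("ref_start", "strand")]
  umap[, family_id := .GRP, by = c("ref_start", "strand", "fam_local")]
  umap[, canonical_umi := umi[1], by = "family_id"]
  umap[, family_size := sum(N), by = "family_id"]
  out <- merge(dt, umap[, c("ref_start", "strand", "umi", "family_id",
                            "canonical_umi", "family_size"), with = FALSE],
               by = c("ref_start", "strand", "umi"), sort = FALSE)
  setorder(out, family_id, read_id)
  out[]
}

# vectorized consensus over many families at once; reads must be
# length-aligned within each family
consensus_core <- function(long, error_rate_post_umi) {
  cap <- error_rate_post_umi
  b <- cnt <- qsum <- qcap <- depth <- c1 <- q1 <- qall <- NULL
  long <- long[b != 5L] # N member bases carry no evidence
  agg <- long[, list(cnt = .N, qsum = sum(pmin(qual, cap))),
              by = c("fid", "pos", "b")]
  setorder(agg, fid, pos, -cnt, b)
  top <- agg[, list(b1 = b[1], c1 = cnt[1], q1 = qsum[1],
                    c2 = if (.N > 1L) cnt[2] else 0L,
                    depth = sum(cnt), qall = sum(qsum)),
             by = c("fid", "pos")]
  tie <- top$c1 == top$c2
  base_out <- ifelse(tie, 5L, top$b1)
  qual_out <- pmax(2L, top$q1 - (top$qall - top$q1))
  qual_out[tie] <- 2L
  err_out <- ifelse(top$depth > 0, (top$depth - top$c1) / top$depth, 0)
  data.table(fid = top$fid, pos = top$pos, base = BASE5[base_out],
             qual = as.integer(qual_out), depth = top$depth,
             err = err_out)
}

#' Call a molecular consensus read from one UMI family
#'
#' Per position, the consensus base is the unique plurality base over the
#' family's non-N member bases; a tie (or zero depth) yields N. Each
#' member's Phred quality is capped at `error_rate_post_umi` before
#' entering the evidence sum; the consensus quality is the summed evidence
#' of agreeing members minus that of disagreeing members, floored at 2.
#' The per-base error fraction is the disagreeing share of the depth.
#'
#' @param bases character vector of the family members' base strings, all
#'   the same length.
#' @param quals Phred+33 quality strings matching `bases`, or NULL for a
#'   flat Q30.
#' @param min_reads minimum family size (default 1); smaller families are
#'   an error here, use [filter_consensus()] for downstream rejection.
#' @param error_rate_post_umi per-member Phred cap (default 30).
#' @return a `consensus_read` list: bases (string), qual, depth,
#'   error_fraction (per-base vectors) and family_size.
#' @export
call_consensus <- function(bases, quals = NULL, min_reads = 1L,
                           error_rate_post_umi = 30L) {
  n <- length(bases)
  if (n < min_reads) {
    stop("family of size ", n, " is below min_reads = ", min_reads)
  }
  if (length(unique(nchar(bases))) != 1) {
    stop("family members must be length-aligned")
  }
  if (is.null(quals)) quals <- strrep(phred_char(30L), nchar(bases))
  long <- explode_reads(bases, fid = rep(1L, n), quals = quals)
  cc <- consensus_core(long, error_rate_post_umi = error_rate_post_umi)
  setorder(cc, pos)
  L <- nchar(bases[1])
  # positions where every member was N never reach consensus_core
  base_v <- rep("N", L); qual_v <- rep(2L, L)
  depth_v <- rep(0L, L); err_v <- rep(0, L)
  base_v[cc$pos] <- cc$base
  qual_v[cc$pos] <- cc$qual
  depth_v[cc$pos] <- cc$depth
  err_v[cc$pos] <- cc$err
  structure(list(bases = paste(base_v, collapse = ""), qual = qual_v,
                 depth = depth_v, error_fraction = err_v, family_size = n),
            class = "consensus_read")
}

#' Call consensus reads for all UMI families
#'
#' Vectorized over the whole read set; the per-family behaviour matches
#' [call_consensus()]. Families smaller than `min_reads` are dropped and
#' reported.
#'
#' @param grouped output of [group_reads_by_umi()] with columns `insert`
#'   (member bases) and `qual` (Phred+33 string).
#' @param min_reads minimum family size to attempt a consensus (default 1).
#' @param error_rate_post_umi per-member Phred cap (default 30).
#' @return list with `consensus`: data.table (family_id, ref_start, strand,
#'   canonical_umi, family_size, bases, qual/depth/error_fraction list
#'   columns) and `rejected`: data.table (family_id, reason).
#' @export
consensus_from_families <- function(grouped, min_reads = 1L,
                                    error_rate_post_umi = 30L) {
  gd <- as.data.table(grouped)
  stopifnot(all(c("family_id", "insert", "family_size") %in% names(gd)))
  small <- unique(gd[gd$family_size < min_reads,
                     c("family_id", "family_size"), with = FALSE])
  rejected <- data.table(family_id = small$family_id,
                         reason = "min_reads")
  gd <- gd[gd$family_size >= min_reads]
  meta <- unique(gd[, c("family_id", "ref_start", "strand",
                        "canonical_umi", "family_size"), with = FALSE])
  setorder(meta, family_id)
  if (nrow(gd) == 0) {
    return(list(consensus = data.table(), rejected = rejected))
  }
  quals <- if ("qual" %in% names(gd)) gd$qual else
    strrep(phred_char(30L), nchar(gd$insert))
  long <- explode_reads(gd$insert, fid = gd$family_id, quals = quals)
  cc <- consensus_core(long, error_rate_post_umi = error_rate_post_umi)
  setorder(cc, fid, pos)
  per <- cc[, list(bases = paste(base, collapse = ""),
                   qual = list(qual), depth = list(depth),
                   error_fraction = list(err)), by = "fid"]
  cons <- merge(meta, per, by.x = "family_id", by.y = "fid")
  list(consensus = cons, rejected = rejected)
}

#' Consensus filtering parameters
#'
#' Defaults follow the standard consensus-filtering recipe for
#' low-frequency variant work: minimum three reads per consensus, per-read
#' mean error at most 5%, per-base quality at least 40, per-base error
#' fraction at most 10%, no-call fraction at most 10%.
#'
#' @param min_reads minimum family size (default 3).
#' @param max_read_error_rate maximum mean per-base error fraction
#'   (default 0.05).
#' @param min_base_quality bases below this Phred quality are masked to N
#'   (default 40).
#' @param max_base_error_rate bases with a larger disagreeing fraction are
#'   masked to N (default 0.1).
#' @param max_no_call_fraction maximum fraction of N bases after masking
#'   (default 0.1).
#' @param min_map_q minimum mapping quality at grouping (default 10).
#' @param umi_edits UMI adjacency edits at grouping (default 1).
#' @return a `consensus_filter_params` list.
#' @export
consensus_filter_params <- function(min_reads = 3L,
                                    max_read_error_rate = 0.05,
                                    min_base_quality = 40L,
                                    max_base_error_rate = 0.1,
                                    max_no_call_fraction = 0.1,
                                    min_map_q = 10L, umi_edits = 1L) {
  stopifnot(min_reads >= 1, max_read_error_rate >= 0,
            max_read_error_rate <= 1, min_base_quality >= 0,
            max_base_error_rate >= 0, max_base_error_rate <= 1,
            max_no_call_fraction >= 0, max_no_call_fraction <= 1)
  structure(list(min_reads = as.integer(min_reads),
                 max_read_error_rate = max_read_error_rate,
                 min_base_quality = as.integer(min_base_quality),
                 max_base_error_rate = max_base_error_rate,
                 max_no_call_fraction = max_no_call_fraction,
                 min_map_q = as.integer(min_map_q),
                 umi_edits = as.integer(umi_edits)),
            class = "consensus_filter_params")
}

#' Filter consensus reads
#'
#' Rejects a consensus read when its family size is below `min_reads`, its
#' mean per-base error fraction exceeds `max_read_error_rate`, or -- after
#' masking individual bases whose quality is below `min_base_quality` or
#' whose error fraction exceeds `max_base_error_rate` to N (quality 2) --
#' its no-call fraction exceeds `max_no_call_fraction`.
#'
#' @param cons consensus data.table from [consensus_from_families()].
#' @param params a [consensus_filter_params()].
#' @return list with `kept` (masked consensus data.table) and `rejected`
#'   (data.table family_id, reason).
#' @export
filter_consensus <- function(cons, params = consensus_filter_params()) {
  cons <- as.data.table(cons)
  n <- nrow(cons)
  reason <- rep(NA_character_, n)
  reason[cons$family_size < params$min_reads] <- "min_reads"
  mean_err <- vapply(cons$error_fraction, mean, numeric(1))
  reason[is.na(reason) &
           mean_err > params$max_read_error_rate] <- "max_read_error_rate"
  bases_new <- cons$bases
  quals_new <- cons$qual
  no_call <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(reason[i])) next
    q <- quals_new[[i]]
    e <- cons$error_fraction[[i]]
    mask <- q < params$min_base_quality | e > params$max_base_error_rate
    if (any(mask)) {
      s <- strsplit(bases_new[i], "")[[1]]
      s[mask] <- "N"
      bases_new[i] <- paste(s, collapse = "")
      q[mask] <- 2L
      quals_new[[i]] <- q
    }
    no_call[i] <- mean(strsplit(bases_new[i], "")[[1]] == "N")
    if (no_call[i] > params$max_no_call_fraction) {
      reason[i] <- "max_no_call_fraction"
    }
  }
  keep <- is.na(reason)
  kept <- cons[keep]
  set(kept, j = "bases", value = bases_new[keep])
  set(kept, j = "qual", value = quals_new[keep])
  list(kept = kept,
       rejected = data.table(family_id = cons$family_id[!keep],
                             reason = reason[!keep]))
}

#' Coordinate-only duplicate collapse (the "no UMI" comparator)
#'
#' Retains one read per (ref_start, strand) key -- highest mean base
#' quality, ties broken by read_id order -- emulating coordinate-based
#' deduplication without molecular identity. Distinct molecules that happen
#' to share coordinates are merged, which is precisely the information loss
#' UMIs repair.
#'
#' @param reads data.table with `read_id`, `ref_start`, `strand`, `insert`,
#'   `qual`.
#' @return data.table of retained reads.
#' @export
raw_duplicate_collapse <- function(reads) {
  dt <- as.data.table(reads)
  uq <- unique(dt$qual)
  mq <- vapply(uq, function(s) mean(utf8ToInt(s) - 33L), numeric(1))
  mean_q <- mq[match(dt$qual, uq)]
  ord <- order(dt$ref_start, dt$strand, -mean_q, dt$read_id)
  dt <- dt[ord]
  dt[!duplicated(dt[, c("ref_start", "strand"), with = FALSE])]
}

#' Write consensus reads as TSV
#'
#' @param cons consensus data.table.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_consensus_tsv <- function(cons, path) {
  out <- data.table(family_id = cons$family_id, ref_start = cons$ref_start,
                    strand = cons$strand, canonical_umi = cons$canonical_umi,
                    family_size = cons$family_size, bases = cons$bases,
                    quals = vapply(cons$qual, paste, "", collapse = ","),
                    depths = vapply(cons$depth, paste, "", collapse = ","))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
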