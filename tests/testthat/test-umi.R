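mk_reads <- function(umis, ref_start = 0L, strand = "+", insert = "ACGT",
                     qual = NULL) {
  n <- length(umis)
  if (is.null(qual)) qual <- strrep("?", nchar(insert)) # Q30
  data.frame(read_id = seq_len(n), ref_start = ref_start, strand = strand,
             umi = umis, insert = insert, qual = qual, mapq = 60L,
             stringsAsFactors = FALSE)
}

test_that("adjacency grouping applies the count-ratio rule", {
  # 5x AAAAAA + 1x AAAAAT: 5 >= 2*1 - 1, one family of six
  g <- group_reads_by_umi(mk_reads(c(rep("AAAAAA", 5), "AAAAAT")))
  expect_length(unique(g$family_id), 1)
  expect_equal(unique(g$family_size), 6)
  expect_equal(unique(g$canonical_umi), "AAAAAA")
  # distance 6 > 1: two families
  g2 <- group_reads_by_umi(mk_reads(c("AAAAAA", "AAAAAA", "TTTTTT",
                                      "TTTTTT")))
  expect_length(unique(g2$family_id), 2)
  # equal counts of 2 fail the ratio rule (2 < 2*2 - 1): two families
  g3 <- group_reads_by_umi(mk_reads(c("AAAA", "AAAA", "AAAT", "AAAT")))
  expect_length(unique(g3$family_id), 2)
  # but a 3-vs-2 split passes (3 >= 2*2 - 1): one family
  g4 <- group_reads_by_umi(mk_reads(c(rep("AAAA", 3), "AAAT", "AAAT")))
  expect_length(unique(g4$family_id), 1)
})

test_that("grouping respects position, strand and mapping quality", {
  r <- rbind(mk_reads(rep("AAAAAA", 2), ref_start = 0L),
             mk_reads(rep("AAAAAA", 2), ref_start = 5L),
             mk_reads(rep("AAAAAA", 2), ref_start = 5L, strand = "-"))
  r$read_id <- seq_len(nrow(r))
  g <- group_reads_by_umi(r)
  expect_length(unique(g$family_id), 3)
  # mapq filter excludes reads
  r$mapq <- c(60L, 5L, rep(60L, 4))
  g2 <- group_reads_by_umi(r, min_map_q = 10)
  expect_equal(nrow(g2), 5)
  # partition: every retained read in exactly one family
  expect_equal(anyDuplicated(g2$read_id), 0L)
  expect_error(group_reads_by_umi(mk_reads(c("AAAA", "AAAAAA"))),
               "length")
})

test_that("random instances match the brute-force adjacency oracle", {
  set.seed(51)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    umis <- replicate(n, paste(sample(c("A", "C", "G", "T"), 4,
                                      replace = TRUE), collapse = ""))
    g <- group_reads_by_umi(mk_reads(umis))
    setkey(g, read_id)
    got <- canon_partition(g$family_id)
    want <- canon_partition(bf_adjacency(umis))
    expect_identical(got, want)
  }
})

test_that("consensus calling votes per position with evidence qualities", {
  # three identical members agree everywhere; per-member cap is Q30
  cc <- call_consensus(rep("ACGT", 3))
  expect_equal(cc$bases, "ACGT")
  expect_equal(cc$qual, rep(90L, 4))
  expect_equal(cc$depth, rep(3L, 4))
  expect_equal(cc$error_fraction, rep(0, 4))
  # {A, A, C}: plurality A, error fraction 1/3, qual 30+30-30
  cc2 <- call_consensus(c("A", "A", "C"))
  expect_equal(cc2$bases, "A")
  expect_equal(cc2$qual, 30L)
  expect_equal(cc2$error_fraction, 1 / 3)
  # {A, C}: tie -> N at quality 2
  cc3 <- call_consensus(c("A", "C"))
  expect_equal(cc3$bases, "N")
  expect_equal(cc3$qual, 2L)
  # member N bases carry no evidence
  cc4 <- call_consensus(c("AN", "AA", "NA"))
  expect_equal(cc4$bases, "AA")
  expect_equal(cc4$depth, c(2L, 2L))
  # all-N column has zero depth
  cc5 <- call_consensus(c("NA", "NA"))
  expect_equal(cc5$bases, "NA")
  expect_equal(cc5$depth, c(0L, 2L))
  expect_error(call_consensus("ACGT", min_reads = 3), "min_reads")
})

test_that("vectorized family consensus equals the single-family caller", {
  set.seed(52)
  plate <- make_unique_dual_plate(design_index_set(2), umi_length = 4)
  sheet <- sample_sheet("s1", "A1", plate)
  cfg <- sim_config(n_fragments = 100,
                    family_size = family_size_spec("poisson1", lambda = 2),
                    oxog_damage_rate = 0.3, oxog_misread_prob = 0.5,
                    reference_length = 150, fragment_length = 40,
                    seed = 53)
  sim <- simulate_experiment(plate, sheet, cfg)
  g <- group_reads_by_umi(sim$reads)
  cons <- consensus_from_families(g)$consensus
  for (fid in sample(cons$family_id, 10)) {
    members <- g[g$family_id == fid]
    one <- call_consensus(members$insert, members$qual)
    row <- cons[cons$family_id == fid]
    expect_equal(row$bases, one$bases)
    expect_equal(row$qual[[1]], one$qual)
    expect_equal(row$error_fraction[[1]], one$error_fraction)
  }
  # determinism
  cons2 <- consensus_from_families(group_reads_by_umi(sim$reads))$consensus
  expect_equal(cons, cons2)
})

test_that("consensus filtering rejects and masks by the stated rules", {
  mk_cons <- function(bases, qual, err, size) {
    data.table(family_id = 1L, ref_start = 0L, strand = "+",
               canonical_umi = "AAAA", family_size = size, bases = bases,
               qual = list(qual), depth = list(rep(size, nchar(bases))),
               error_fraction = list(err))
  }
  L <- 20
  perfect <- mk_cons(strrep("A", L), rep(90L, L), rep(0, L), 5L)
  f <- filter_consensus(perfect)
  expect_equal(nrow(f$kept), 1)
  expect_equal(f$kept$bases, strrep("A", L))
  # family of 2 rejected at min_reads 3
  small <- mk_cons(strrep("A", L), rep(90L, L), rep(0, L), 2L)
  fs <- filter_consensus(small)
  expect_equal(nrow(fs$kept), 0)
  expect_equal(fs$rejected$reason, "min_reads")
  # 15% of bases masked by low quality -> no-call rejection at 10%
  q <- rep(90L, L)
  q[1:3] <- 10L
  masked <- mk_cons(strrep("A", L), q, rep(0, L), 5L)
  fm <- filter_consensus(masked)
  expect_equal(nrow(fm$kept), 0)
  expect_equal(fm$rejected$reason, "max_no_call_fraction")
  # a single high-error base is masked but the read survives
  e <- rep(0, L)
  e[5] <- 0.4
  he <- mk_cons(strrep("A", L), rep(90L, L), e, 5L)
  fh <- filter_consensus(he)
  expect_equal(substr(fh$kept$bases, 5, 5), "N")
  expect_equal(fh$kept$qual[[1]][5], 2L)
  # mean read error above 5% rejects outright
  bad <- mk_cons(strrep("A", L), rep(90L, L), rep(0.06, L), 5L)
  expect_equal(filter_consensus(bad)$rejected$reason,
               "max_read_error_rate")
})

test_that("coordinate-only collapse keeps one read per position key", {
  r <- mk_reads(c("AAAA", "CCCC"), ref_start = 0L)
  expect_equal(nrow(raw_duplicate_collapse(r)), 1)
  r2 <- rbind(mk_reads("AAAA", ref_start = 0L),
              mk_reads("AAAA", ref_start = 3L))
  r2$read_id <- 1:2
  expect_equal(nrow(raw_duplicate_collapse(r2)), 2)
  # simulation: retained count == distinct (start, strand) keys
  set.seed(54)
  plate <- make_unique_dual_plate(design_index_set(2), umi_length = 4)
  sheet <- sample_sheet("s1", "A1", plate)
  cfg <- sim_config(n_fragments = 5000,
                    family_size = family_size_spec("geometric1", p = 0.5),
                    reference_length = 300, fragment_length = 50,
                    seed = 55)
  sim <- simulate_experiment(plate, sheet, cfg)
  col <- raw_duplicate_collapse(sim$reads)
  keys <- unique(paste(sim$reads$ref_start, sim$reads$strand))
  expect_equal(nrow(col), length(keys))
})

test_that("consensus reduces oxoG artifact carriage versus raw reads", {
  plate <- fixture_dual_plate(2, umi_length = 6)
  sheet <- sample_sheet("s1", "A1", plate)
  for (seed in 1:10) {
    cfg <- sim_config(n_fragments = 400,
                      family_size = family_size_spec("degenerate", k = 4),
                      oxog_damage_rate = 0.5, oxog_misread_prob = 0.5,
                      reference_length = 400, fragment_length = 100,
                      seed = seed)
    sim <- simulate_experiment(plate, sheet, cfg)
    raw_frac <- mean(sim$truth$oxo_misread)
    reads <- merge(sim$reads,
                   sim$truth[, c("read_id", "oxo_pos"), with = FALSE],
                   by = "read_id")
    g <- group_reads_by_umi(reads)
    cons <- consensus_from_families(g, min_reads = 3L)$consensus
    # artifact present in consensus: consensus base at the damaged
    # position differs from the reference
    ref_bases <- strsplit(sim$reference, "")[[1]]
    art <- vapply(seq_len(nrow(cons)), function(i) {
      mem <- g[g$family_id == cons$family_id[i]]
      pos <- mem$oxo_pos[!is.na(mem$oxo_pos)][1]
      if (length(pos) == 0 || is.na(pos)) return(FALSE)
      off <- pos - cons$ref_start[i] + 1L
      b <- substr(cons$bases[i], off, off)
      b != "N" && b != ref_bases[pos + 1L]
    }, logical(1))
    expect_lt(mean(art), raw_frac)
  }
})
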