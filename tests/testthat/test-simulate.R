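test_that("adapter-arm draws follow the independence model per stage", {
  plate <- fixture_dual_plate(4)
  # no contamination: both arms always from the sample well
  set.seed(1)
  arms0 <- draw_adapter_arms(1000, "A1", plate)
  expect_true(all(arms0$i7_well == "A1" & arms0$i5_well == "A1"))

  # duplex stage: each arm independently from the contaminant at rate c
  c <- 0.01
  n <- 2e5
  set.seed(2)
  arms <- draw_adapter_arms(n, "A1", plate,
                            contamination_spec("A1", "A2", c), "duplex")
  both <- mean(arms$i7_well == "A2" & arms$i5_well == "A2")
  one <- mean(xor(arms$i7_well == "A2", arms$i5_well == "A2"))
  expect_lt(abs(both - c^2), 3 * sqrt(c^2 * (1 - c^2) / n))
  p1 <- 2 * c * (1 - c)
  expect_lt(abs(one - p1), 3 * sqrt(p1 * (1 - p1) / n))

  # oligo stage with an i7-arm leak: the i5 arm is never contaminated
  set.seed(3)
  armso <- draw_adapter_arms(n, "A1", plate,
                             contamination_spec("A1", "A2", c, arm = "i7"),
                             "oligo")
  expect_true(all(armso$i5_well == "A1"))
  f7 <- mean(armso$i7_well == "A2")
  expect_lt(abs(f7 - c), 3 * sqrt(c * (1 - c) / n))
})

test_that("index hopping swaps indices to other pool members", {
  pool <- paste0("A", 1:16)
  i7 <- rep("A1", 1e5)
  i5 <- rep("A1", 1e5)
  # h = 0 is the identity
  set.seed(4)
  h0 <- apply_index_hopping(i7, i5, pool, 0)
  expect_true(all(h0$i7_well == "A1" & !h0$hopped_i7))
  # single-plex pool cannot hop
  expect_warning(h1 <- apply_index_hopping(i7, i5, "A1", 0.01),
                 "nothing to hop")
  expect_true(all(!h1$hopped_i7 & !h1$hopped_i5))
  # closed form: P(>= 1 hopped index) = 1 - (1 - h)^2
  h <- 0.004
  set.seed(5)
  hp <- apply_index_hopping(i7, i5, pool, h)
  anyhop <- mean(hp$hopped_i7 | hp$hopped_i5)
  p <- 1 - (1 - h)^2
  expect_lt(abs(anyhop - p), 3 * sqrt(p * (1 - p) / 1e5))
  # destinations are other pool members, never the origin
  expect_true(all(hp$i7_well[hp$hopped_i7] != "A1"))
  expect_true(all(hp$i7_well[hp$hopped_i7] %in% pool))
})

test_that("index sequencing error is substitution-only at the stated rate", {
  seqs <- rep("ACGTACGT", 1e5)
  set.seed(6)
  m0 <- apply_index_sequencing_error(seqs, 0)
  expect_identical(m0$seqs, seqs)
  e <- 0.005
  set.seed(7)
  m <- apply_index_sequencing_error(seqs, e)
  p <- 1 - (1 - e)^8
  expect_lt(abs(mean(m$changed) - p), 3 * sqrt(p * (1 - p) / 1e5))
  # changed reads differ at >= 1 position, unchanged reads are identical
  expect_true(all(m$seqs[!m$changed] == "ACGTACGT"))
  d <- mapply(hamming_str, m$seqs[m$changed],
              rep("ACGTACGT", sum(m$changed)))
  expect_true(all(d >= 1))
  expect_true(all(nchar(m$seqs) == 8))
})

test_that("amplification emits UMI-sharing families with per-copy misreads", {
  mols <- data.frame(molecule_id = 1:500,
                     insert = strrep("C", 20),
                     oxo_offset = 5L, oxo_alt = "A")
  # degenerate family size 1: one read per molecule
  set.seed(8)
  r1 <- amplify_with_umi(mols, family_size_spec("degenerate", k = 1), 0)
  expect_equal(nrow(r1), 500)
  expect_true(all(!r1$oxo_shown))
  # p_mis = 1: every copy of a damaged molecule shows the artifact
  set.seed(9)
  r2 <- amplify_with_umi(mols, family_size_spec("degenerate", k = 3), 1)
  expect_true(all(r2$oxo_shown))
  expect_true(all(substr(r2$insert, 5, 5) == "A"))
  # p_mis = 0.5, family size 6: binomial mean 3 artifact reads per family
  set.seed(10)
  big <- data.frame(molecule_id = 1:10000, insert = strrep("C", 20),
                    oxo_offset = 5L, oxo_alt = "A")
  r3 <- amplify_with_umi(big, family_size_spec("degenerate", k = 6), 0.5)
  mean_art <- mean(tapply(r3$oxo_shown, r3$molecule_id, sum))
  se <- sqrt(6 * 0.25 / 10000)
  expect_lt(abs(mean_art - 3), 3 * se)
})

test_that("zero-noise simulation reproduces plate indices exactly", {
  plate <- fixture_dual_plate(4)
  sheet <- sample_sheet(c("s1", "s2", "s3"), c("A1", "A2", "A3"), plate)
  cfg <- sim_config(n_fragments = 500, seed = 21,
                    reference_length = 300, fragment_length = 100)
  sim <- simulate_experiment(plate, sheet, cfg)
  wi <- match(sim$truth$true_well, plate$wells$well)
  expect_identical(sim$reads$i7_obs, plate$wells$i7[wi])
  expect_identical(sim$reads$i5_obs, plate$wells$i5[wi])
  expect_true(all(nchar(sim$reads$umi_obs) == 6))
  expect_true(all(nchar(sim$reads$insert) == 100))
})

test_that("simulation is deterministic given the seed", {
  plate <- fixture_dual_plate(3)
  sheet <- sample_sheet(c("s1", "s2"), c("A1", "A2"), plate)
  cfg <- sim_config(n_fragments = 300, hop_rate = 0.01,
                    index_error_rate = 0.01,
                    family_size = family_size_spec("poisson1", lambda = 2),
                    oxog_damage_rate = 0.1, oxog_misread_prob = 0.5,
                    reference_length = 400, fragment_length = 80,
                    seed = 33)
  s1 <- simulate_experiment(plate, sheet, cfg)
  s2 <- simulate_experiment(plate, sheet, cfg)
  expect_equal(s1$reads, s2$reads)
  expect_equal(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  p1 <- write_fastq(s1, file.path(d1, "a"))
  p2 <- write_fastq(s2, file.path(d1, "b"))
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }
})

test_that("read conservation and truth tags audit cleanly", {
  plate <- fixture_dual_plate(4)
  sheet <- sample_sheet(c("s1", "s2"), c("A1", "A2"), plate)
  cfg <- sim_config(n_fragments = 2000, hop_rate = 0.01,
                    index_error_rate = 0.005,
                    contamination = contamination_spec("A1", "A3", 0.02),
                    family_size = family_size_spec("poisson1", lambda = 1),
                    reference_length = 300, fragment_length = 100,
                    seed = 44)
  sim <- simulate_experiment(plate, sheet, cfg)
  # conservation: reads == sum of family sizes over molecules
  fam <- table(sim$truth$molecule_id)
  expect_equal(nrow(sim$reads), sum(fam))
  # every observed/true index discrepancy is explained by an event tag,
  # and untagged reads match their well's indices exactly
  tr <- sim$truth
  wi <- match(tr$true_well, plate$wells$well)
  mism7 <- sim$reads$i7_obs != plate$wells$i7[wi]
  mism5 <- sim$reads$i5_obs != plate$wells$i5[wi]
  expl7 <- tr$contaminated_i7_arm | tr$hopped_i7 | tr$err_i7
  expl5 <- tr$contaminated_i5_arm | tr$hopped_i5 | tr$err_i5
  expect_true(all(!mism7 | expl7))
  expect_true(all(!mism5 | expl5))
  expect_true(all(!(mism7 & !expl7)) && all(!(mism5 & !expl5)))
})

test_that("oligo-stage i7 leak never contaminates the i5 arm", {
  plate <- fixture_dual_plate(4)
  sheet <- sample_sheet("s1", "A1", plate)
  cfg <- sim_config(n_fragments = 20000,
                    contamination = contamination_spec("A1", "A2", 0.01,
                                                       arm = "i7"),
                    contamination_stage = "oligo",
                    reference_length = 200, fragment_length = 50,
                    seed = 55)
  sim <- simulate_experiment(plate, sheet, cfg)
  expect_true(all(!sim$truth$contaminated_i5_arm))
  expect_gt(sum(sim$truth$contaminated_i7_arm), 0)
})

test_that("spiked variants appear at their stated allele fraction", {
  plate <- fixture_dual_plate(2)
  sheet <- sample_sheet("s1", "A1", plate)
  cfg0 <- sim_config(seed = 66, reference_length = 500,
                     fragment_length = 100)
  ref <- sim_reference(cfg0)
  vars <- choose_spikein_variants(ref, 250L, 0.01)
  cfg <- sim_config(n_fragments = 1e5, reference_length = 500,
                    fragment_length = 100, variants = vars, seed = 66)
  sim <- simulate_experiment(plate, sheet, cfg)
  expect_identical(sim$reference, ref)
  cover <- sim$reads$ref_start <= 250 & 250 < sim$reads$ref_start + 100
  alt <- substr(sim$reads$insert, 250 - sim$reads$ref_start + 1,
                250 - sim$reads$ref_start + 1) == vars$alt
  af <- sum(alt & cover) / sum(cover)
  expect_lt(abs(af - 0.01), 3 * sqrt(0.01 * 0.99 / sum(cover)))
})

test_that("FASTQ output follows the four-file dual-index convention", {
  plate <- fixture_dual_plate(3, umi_length = 6)
  sheet <- sample_sheet(c("s1", "s2"), c("A1", "A2"), plate)
  cfg <- sim_config(n_fragments = 50, seed = 77,
                    reference_length = 200, fragment_length = 60)
  sim <- simulate_experiment(plate, sheet, cfg)
  d <- withr::local_tempdir()
  paths <- write_fastq(sim, file.path(d, "run"))
  nrec <- vapply(paths, function(p) length(readLines(p)) / 4, 0)
  expect_true(all(nrec == nrow(sim$reads)))
  i1 <- readLines(paths["I1"])
  expect_true(all(nchar(i1[seq(2, length(i1), by = 4)]) == 14)) # 8 + 6
  back <- read_fastq_set(file.path(d, "run"), umi_length = 6)
  expect_identical(back$i7_obs, sim$reads$i7_obs)
  expect_identical(back$i5_obs, sim$reads$i5_obs)
  expect_identical(back$umi_obs, sim$reads$umi_obs)
  expect_identical(back$insert, sim$reads$insert)
})
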