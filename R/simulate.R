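#' @import data.table
NULL

# Phred+33 character for a quality score
phred_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)

#' Describe a PCR duplicate family-size distribution
#'
#' Family size is the number of sequenced copies of one pre-PCR molecule.
#' Supported distributions: `degenerate` (always `k`), `poisson1`
#' (1 + Poisson(lambda)) and `geometric1` (1 + Geometric(p)); all guarantee
#' at least one read per molecule.
#'
#' @param dist one of "degenerate", "poisson1", "geometric1".
#' @param k,lambda,p distribution parameters.
#' @return a `family_size_spec` list.
#' @export
family_size_spec <- function(dist = c("poisson1", "degenerate", "geometric1"),
                             k = 1L, lambda = 2, p = 0.5) {
  dist <- match.arg(dist)
  if (dist == "degenerate" && k < 1) stop("k must be >= 1")
  if (dist == "poisson1" && lambda < 0) stop("lambda must be >= 0")
  if (dist == "geometric1" && (p <= 0 || p > 1)) stop("p must be in (0, 1]")
  structure(list(dist = dist, k = as.integer(k), lambda = lambda, p = p),
            class = "family_size_spec")
}

#' Draw family sizes
#' @param n number of molecules.
#' @param spec a [family_size_spec()].
#' @return integer vector of n sizes, all >= 1.
#' @export
draw_family_sizes <- function(n, spec) {
  switch(spec$dist,
    degenerate = rep.int(spec$k, n),
    poisson1 = rpois(n, spec$lambda) + 1L,
    geometric1 = rgeom(n, spec$p) + 1L
  )
}

#' Specify adapter cross-contamination events
#'
#' A contamination entry states that the adapter pool of `target` wells
#' contains adapter material from `source` wells at fraction `rate`.
#' With duplexed-adapter contamination (`arm = "both"`) both the i7-bearing
#' and the i5-bearing strand of the contaminating adapter enter the pool, so
#' each arm of a fragment is independently swapped at rate `rate`. With
#' single-stranded-oligo contamination only the named arm (`"i7"` or
#' `"i5"`) ever leaks, producing a directional (skewed) cross-talk pattern.
#'
#' @param target,source well ids.
#' @param rate contamination fraction in [0, 1].
#' @param arm "both" (duplex stage), "i7" or "i5" (oligo stage).
#' @return a data.frame usable as the `contamination` field of
#'   [sim_config()]; rbind entries to combine.
#' @export
contamination_spec <- function(target, source, rate, arm = "both") {
  stopifnot(length(target) == length(source), length(rate) %in%
              c(1L, length(target)))
  data.frame(target = target, source = source, rate = rate,
             arm = arm, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects every tunable of the read simulator. All rates are per the unit
#' stated: `hop_rate` is per read per index, `index_error_rate` per index
#' base, `oxog_damage_rate` per molecule, `oxog_misread_prob` per PCR copy
#' of a damaged base.
#'
#' @param n_fragments molecules per sample: a single number, or a named
#'   vector keyed by sample_id.
#' @param contamination a data.frame from [contamination_spec()], or NULL.
#' @param contamination_stage "duplex" (arm = "both" entries) or "oligo"
#'   (directional "i7"/"i5" entries).
#' @param hop_rate per-read per-index probability of index hopping in the
#'   capture pool.
#' @param index_error_rate per-base substitution probability on index and
#'   UMI reads (in [0, 0.25]).
#' @param family_size a [family_size_spec()].
#' @param reference_length length of the random reference (bp).
#' @param fragment_length insert length of every molecule (bp); the paper's
#'   libraries were sheared to 250 bp.
#' @param variants data.frame with columns `pos` (0-based reference
#'   position), `alt` (base) and `af` (expected allele fraction), or NULL.
#' @param oxog_damage_rate probability that a molecule carries 8-oxoG
#'   damage at one uniformly chosen G/C reference position in its insert.
#' @param oxog_misread_prob probability that one PCR copy reads the damaged
#'   base as the transversion allele (G>T on reference-G, C>A on
#'   reference-C).
#' @param seed integer RNG seed recorded in outputs; `set.seed()` is called
#'   by [simulate_experiment()].
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_fragments = 1000L,
                       contamination = NULL,
                       contamination_stage = c("duplex", "oligo"),
                       hop_rate = 0,
                       index_error_rate = 0,
                       family_size = family_size_spec("degenerate", k = 1L),
                       reference_length = 1000L,
                       fragment_length = 250L,
                       variants = NULL,
                       oxog_damage_rate = 0,
                       oxog_misread_prob = 0,
                       seed = 1L) {
  contamination_stage <- match.arg(contamination_stage)
  rates <- c(hop_rate, index_error_rate, oxog_damage_rate, oxog_misread_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (index_error_rate > 0.25) stop("index_error_rate must be <= 0.25")
  if (fragment_length > reference_length) {
    stop("fragment_length exceeds reference_length")
  }
  if (!is.null(contamination)) {
    stopifnot(all(c("target", "source", "rate", "arm") %in%
                    names(contamination)))
    if (any(contamination$rate < 0 | contamination$rate > 1)) {
      stop("contamination rates must be in [0, 1]")
    }
    ok_arms <- if (contamination_stage == "duplex") "both" else c("i7", "i5")
    if (!all(contamination$arm %in% ok_arms)) {
      stop("contamination arm entries incompatible with stage '",
           contamination_stage, "'")
    }
    tot <- tapply(contamination$rate,
                  paste(contamination$target, contamination$arm),
                  sum)
    if (any(tot > 1)) stop("contamination rates for a target sum to > 1")
  }
  if (!is.null(variants)) {
    stopifnot(all(c("pos", "alt", "af") %in% names(variants)))
    if (any(variants$af < 0 | variants$af > 1)) stop("af must be in [0, 1]")
    if (any(variants$pos < 0 | variants$pos >= reference_length)) {
      stop("variant position outside reference")
    }
  }
  structure(list(
    n_fragments = n_fragments, contamination = contamination,
    contamination_stage = contamination_stage, hop_rate = hop_rate,
    index_error_rate = index_error_rate, family_size = family_size,
    reference_length = as.integer(reference_length),
    fragment_length = as.integer(fragment_length), variants = variants,
    oxog_damage_rate = oxog_damage_rate,
    oxog_misread_prob = oxog_misread_prob, seed = as.integer(seed)
  ), class = "sim_config")
}

# n random k-mers; for small k index into the enumerated k-mer table so the
# string cache is shared across reads
random_kmers <- function(n, k) {
  if (k == 0) return(rep.int("", n))
  if (4^k <= 65536) {
    tbl <- all_kmers(k)
    tbl[sample.int(length(tbl), n, replace = TRUE)]
  } else {
    m <- matrix(sample(DNA_BASES, n * k, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m))
  }
}

all_kmers <- function(k) {
  g <- do.call(expand.grid, rep(list(DNA_BASES), k))
  do.call(paste0, rev(g))
}

#' Draw the adapter arms of fragments from a contaminated pool
#'
#' The i7-bearing and i5-bearing adapter arms of each fragment are drawn
#' independently from the sample's adapter pool. Under duplex-stage
#' contamination both arms of the contaminating adapter are present, so
#' each arm independently originates from contaminant well X with
#' probability c(X) -- the mechanism by which dual-matched indices reduce
#' full misassignment to approximately c squared. Under oligo-stage
#' contamination only the leaked strand's arm is ever swapped.
#'
#' @param n number of fragments.
#' @param sample_well the well whose library is being built.
#' @param plate an `adapter_plate`.
#' @param contamination contamination data.frame (see
#'   [contamination_spec()]); entries for other targets are ignored.
#' @param contamination_stage "duplex" or "oligo".
#' @return data.frame with columns `i7_well` and `i5_well` (source well of
#'   each arm).
#' @export
draw_adapter_arms <- function(n, sample_well, plate, contamination = NULL,
                              contamination_stage = "duplex") {
  plate_well_index(plate, sample_well)
  draw_arm <- function(arm) {
    if (is.null(contamination)) return(rep.int(sample_well, n))
    keep <- contamination$target == sample_well &
      contamination$arm %in% (if (contamination_stage == "duplex") "both"
                              else arm)
    entries <- contamination[keep, , drop = FALSE]
    if (nrow(entries) == 0) return(rep.int(sample_well, n))
    tot <- sum(entries$rate)
    if (tot > 1) stop("contamination rates sum to > 1")
    sample(c(entries$source, sample_well), n, replace = TRUE,
           prob = c(entries$rate, 1 - tot))
  }
  data.frame(i7_well = draw_arm("i7"), i5_well = draw_arm("i5"),
             stringsAsFactors = FALSE)
}

#' Apply index hopping within a multiplexed capture pool
#'
#' Free adapter in a multiplexed capture can re-prime library molecules
#' during post-capture PCR, swapping one index for that of another pooled
#' library. Each index of each read independently hops with probability
#' `hop_rate` to the corresponding index of a uniformly chosen other pool
#' member well.
#'
#' @param i7_well,i5_well character vectors: current source well of each
#'   read's i7 and i5 index.
#' @param pool_wells wells of the libraries in the capture pool.
#' @param hop_rate per-read per-index hop probability.
#' @return data.frame with columns `i7_well`, `i5_well`, `hopped_i7`,
#'   `hopped_i5`.
#' @export
apply_index_hopping <- function(i7_well, i5_well, pool_wells, hop_rate) {
  n <- length(i7_well)
  out <- data.frame(i7_well = i7_well, i5_well = i5_well,
                    hopped_i7 = logical(n), hopped_i5 = logical(n),
                    stringsAsFactors = FALSE)
  if (hop_rate <= 0 || n == 0) return(out)
  if (length(pool_wells) < 2) {
    warning("pool of size 1: nothing to hop to; hopping is a no-op")
    return(out)
  }
  P <- length(pool_wells)
  hop_one <- function(cur) {
    hops <- which(runif(n) < hop_rate)
    new <- cur
    if (length(hops) > 0) {
      pos <- match(cur[hops], pool_wells)
      r <- integer(length(hops))
      known <- !is.na(pos)
      # skip the current well so the destination is a *different* member
      r[known] <- {
        d <- sample.int(P - 1L, sum(known), replace = TRUE)
        d + (d >= pos[known])
      }
      r[!known] <- sample.int(P, sum(!known), replace = TRUE)
      new[hops] <- pool_wells[r]
    }
    list(well = new, hopped = seq_len(n) %in% hops)
  }
  h7 <- hop_one(i7_well)
  h5 <- hop_one(i5_well)
  out$i7_well <- h7$well
  out$i5_well <- h5$well
  out$hopped_i7 <- h7$hopped
  out$hopped_i5 <- h5$hopped
  out
}

# substitution-only per-base error on equal-length sequences; returns the
# mutated sequences and a logical "any base changed" flag per sequence
mutate_bases <- function(seqs, error_rate) {
  n <- length(seqs)
  changed <- logical(n)
  if (n == 0 || error_rate <= 0 || nchar(seqs[1]) == 0) {
    return(list(seqs = seqs, changed = changed))
  }
  L <- nchar(seqs[1])
  alt_mat <- matrix(c("C", "G", "T",  "A", "G", "T",
                      "A", "C", "T",  "A", "C", "G"), nrow = 3)
  chunk <- max(1L, as.integer(2e7 / L))
  for (st in seq(1L, n, by = chunk)) {
    en <- min(n, st + chunk - 1L)
    m <- en - st + 1L
    hit <- which(runif(m * L) < error_rate)
    if (length(hit) == 0) next
    ri <- (hit - 1L) %/% L + st
    pi <- (hit - 1L) %% L + 1L
    cur <- substring(seqs[ri], pi, pi)
    repl <- alt_mat[cbind(sample.int(3L, length(ri), replace = TRUE),
                          match(cur, DNA_BASES))]
    rid <- data.table::rowidv(ri)
    for (round in seq_len(max(rid))) {
      sel <- rid == round
      idx <- ri[sel]
      x <- seqs[idx]
      substr(x, pi[sel], pi[sel]) <- repl[sel]
      seqs[idx] <- x
    }
    changed[unique(ri)] <- TRUE
  }
  list(seqs = seqs, changed = changed)
}

#' Apply index-read sequencing error
#'
#' Each base of each sequence is independently substituted to a uniformly
#' chosen different base with probability `error_rate`
#' (substitution-only model; fixed-cycle index reads do not shift).
#'
#' @param seqs character vector of equal-length sequences.
#' @param error_rate per-base substitution probability.
#' @return list with elements `seqs` (mutated) and `changed` (logical, any
#'   base substituted).
#' @export
apply_index_sequencing_error <- function(seqs, error_rate) {
  mutate_bases(seqs, error_rate)
}

#' Amplify molecules into UMI-sharing PCR duplicate reads
#'
#' Each molecule emits k >= 1 reads drawn from the family-size
#' distribution; all copies share the molecule's UMI and coordinates. For a
#' molecule carrying 8-oxoG damage, each copy independently reads the
#' damaged base as the transversion allele with probability
#' `oxog_misread_prob`, otherwise as the reference base -- the per-copy
#' randomness that molecular consensus exploits.
#'
#' @param molecules data.frame/data.table with one row per molecule,
#'   columns `molecule_id`, `insert` (molecule insert bases), `oxo_offset`
#'   (1-based offset of the damaged base within the insert, NA if
#'   undamaged) and `oxo_alt` (artifact base).
#' @param family_size a [family_size_spec()].
#' @param oxog_misread_prob per-copy artifact probability.
#' @return data.table with one row per read: `molecule_id`, `insert`,
#'   `oxo_shown`.
#' @export
amplify_with_umi <- function(molecules, family_size, oxog_misread_prob = 0) {
  molecules <- as.data.table(molecules)
  M <- nrow(molecules)
  k <- draw_family_sizes(M, family_size)
  idx <- rep.int(seq_len(M), k)
  reads <- data.table(molecule_id = molecules$molecule_id[idx],
                      insert = molecules$insert[idx],
                      oxo_shown = FALSE)
  damaged <- !is.na(molecules$oxo_offset[idx])
  if (any(damaged) && oxog_misread_prob > 0) {
    show <- damaged & runif(nrow(reads)) < oxog_misread_prob
    if (any(show)) {
      w <- which(show)
      off <- molecules$oxo_offset[idx[w]]
      x <- reads$insert[w]
      substr(x, off, off) <- molecules$oxo_alt[idx[w]]
      reads[w, insert := x]
      reads[w, oxo_shown := TRUE]
    }
  }
  reads
}

#' Reference sequence implied by a simulation config
#'
#' The simulator draws its uniform-random reference as the first RNG use
#' after seeding, so the reference is a pure function of
#' (`seed`, `reference_length`). This helper reproduces it without running
#' the full simulation -- useful for choosing spike-in variant alleles
#' before simulating.
#'
#' @param config a [sim_config()].
#' @return the reference sequence string.
#' @export
sim_reference <- function(config) {
  set.seed(config$seed)
  paste(sample(DNA_BASES, config$reference_length, replace = TRUE),
        collapse = "")
}

#' Choose spike-in variant alleles on a reference
#'
#' Picks, per position, an alternate allele either inside or outside the
#' 8-oxoG artifact class (C>A / G>T). Outside the class, the first
#' eligible base in A<C<G<T order is taken, so the choice is
#' deterministic; positions whose reference base cannot support the
#' requested class are dropped.
#'
#' @param reference reference sequence string.
#' @param positions 0-based positions.
#' @param af expected allele fraction(s), recycled.
#' @param oxog_class if TRUE produce C>A / G>T alleles (only possible at
#'   C/G reference positions); if FALSE avoid that class.
#' @return data.frame with columns pos, alt, af, suitable for the
#'   `variants` field of [sim_config()].
#' @export
choose_spikein_variants <- function(reference, positions, af,
                                    oxog_class = FALSE) {
  ref <- strsplit(reference, "")[[1]][positions + 1L]
  af <- rep_len(af, length(positions))
  if (oxog_class) {
    keep <- ref %in% c("C", "G")
    alt <- ifelse(ref == "C", "A", "T")
    return(data.frame(pos = positions[keep], alt = alt[keep],
                      af = af[keep], stringsAsFactors = FALSE))
  }
  alt <- vapply(ref, function(r) {
    banned <- c(r, if (r == "C") "A", if (r == "G") "T")
    setdiff(DNA_BASES, banned)[1]
  }, "", USE.NAMES = FALSE)
  data.frame(pos = positions, alt = alt, af = af, stringsAsFactors = FALSE)
}

#' Simulate a multiplexed sequencing experiment
#'
#' Composes the full generative model, per molecule: reference draw,
#' variant allele assignment at the stated allele fraction, 8-oxoG damage,
#' independent adapter-arm draw (contamination), UMI assignment, PCR
#' amplification, index hopping in the capture pool, and index-read
#' sequencing error. Every read carries hidden truth fields that never
#' influence demultiplexing.
#'
#' @param plate an `adapter_plate`.
#' @param sheet a `sample_sheet`; all samples form one capture pool.
#' @param config a [sim_config()].
#' @return a `sim_experiment` list with elements `reads` (data.table:
#'   read_id, i7_obs, i5_obs, umi_obs, insert, qual, ref_start, strand,
#'   mapq), `truth` (per-read event tags and provenance), `reference`,
#'   `plate`, `sheet`, `config`. Deterministic given `config$seed`.
#' @export
simulate_experiment <- function(plate, sheet, config) {
  validate_plate(plate)
  validate_sample_sheet(sheet, plate)
  set.seed(config$seed)
  ref_len <- config$reference_length
  frag_len <- config$fragment_length
  reference <- paste(sample(DNA_BASES, ref_len, replace = TRUE),
                     collapse = "")
  ref_bases <- strsplit(reference, "")[[1]]

  nf <- config$n_fragments
  if (!is.null(names(nf))) {
    missing <- setdiff(sheet$sample_id, names(nf))
    if (length(missing) > 0) stop("n_fragments missing for: ",
                                  paste(missing, collapse = ", "))
    n_per <- as.integer(nf[sheet$sample_id])
  } else {
    n_per <- rep.int(as.integer(nf[1]), nrow(sheet))
  }

  M <- sum(n_per)
  mol <- data.table(
    molecule_id = seq_len(M),
    sample = rep(sheet$sample_id, n_per),
    well = rep(sheet$well, n_per)
  )
  mol[, ref_start := sample.int(ref_len - frag_len + 1L, M,
                                replace = TRUE) - 1L]
  mol[, strand := sample(c("+", "-"), M, replace = TRUE)]
  mol[, umi := random_kmers(M, plate$umi_length)]
  mol[, insert := substring(reference, ref_start + 1L,
                            ref_start + frag_len)]

  # molecular variant alleles (all PCR copies of a carrier share the alt)
  if (!is.null(config$variants) && nrow(config$variants) > 0) {
    v <- config$variants
    for (i in seq_len(nrow(v))) {
      pos <- v$pos[i]
      cover <- which(mol$ref_start <= pos & pos < mol$ref_start + frag_len)
      if (length(cover) == 0) next
      carrier <- cover[runif(length(cover)) < v$af[i]]
      if (length(carrier) == 0) next
      off <- pos - mol$ref_start[carrier] + 1L
      x <- mol$insert[carrier]
      substr(x, off, off) <- v$alt[i]
      mol[carrier, insert := x]
    }
  }

  # oxoG damage: one uniformly chosen G/C position per damaged molecule;
  # reference-G reads as G>T, reference-C (G on the minus strand) as C>A
  mol[, oxo_offset := NA_integer_]
  mol[, oxo_alt := NA_character_]
  if (config$oxog_damage_rate > 0) {
    gc_pos <- which(ref_bases %in% c("G", "C"))       # 1-based
    cum <- c(0L, cumsum(as.integer(seq_len(ref_len) %in% gc_pos)))
    damaged <- which(runif(M) < config$oxog_damage_rate)
    if (length(damaged) > 0) {
      s <- mol$ref_start[damaged]                      # 0-based
      n_elig <- cum[s + frag_len + 1L] - cum[s + 1L]
      keep <- n_elig > 0
      damaged <- damaged[keep]
      if (length(damaged) > 0) {
        s <- s[keep]
        n_elig <- n_elig[keep]
        pick <- floor(runif(length(damaged)) * n_elig) + 1L
        pos1 <- gc_pos[cum[s + 1L] + pick]             # 1-based ref position
        mol[damaged, oxo_offset := pos1 - s]           # 1-based in insert
        mol[damaged, oxo_alt := ifelse(ref_bases[pos1] == "G", "T", "A")]
      }
    }
  }

  # adapter arms per sample (contamination acts on the adapter pool)
  mol[, i7_well := well]
  mol[, i5_well := well]
  if (!is.null(config$contamination)) {
    for (wl in unique(mol$well)) {
      rows <- which(mol$well == wl)
      arms <- draw_adapter_arms(length(rows), wl, plate,
                                config$contamination,
                                config$contamination_stage)
      mol[rows, `:=`(i7_well = arms$i7_well, i5_well = arms$i5_well)]
    }
  }

  # PCR amplification with per-copy oxoG misreads
  amp <- amplify_with_umi(
    mol[, .(molecule_id, insert, oxo_offset, oxo_alt)],
    config$family_size, config$oxog_misread_prob
  )
  midx <- amp$molecule_id
  nread <- nrow(amp)

  reads <- data.table(
    read_id = seq_len(nread),
    i7_well = mol$i7_well[midx],
    i5_well = mol$i5_well[midx]
  )

  # index hopping in the multiplexed capture pool
  pool_wells <- sheet$well
  if (config$hop_rate > 0 && length(pool_wells) > 1) {
    hp <- apply_index_hopping(reads$i7_well, reads$i5_well, pool_wells,
                              config$hop_rate)
    reads[, `:=`(i7_well = hp$i7_well, i5_well = hp$i5_well)]
    hopped_i7 <- hp$hopped_i7
    hopped_i5 <- hp$hopped_i5
  } else {
    if (config$hop_rate > 0 && length(pool_wells) == 1) {
      warning("pool of size 1: nothing to hop to; hopping is a no-op")
    }
    hopped_i7 <- hopped_i5 <- logical(nread)
  }

  wi <- plate_well_index(plate, reads$i7_well)
  i7_obs <- plate$wells$i7[wi]
  i5_obs <- plate$wells$i5[plate_well_index(plate, reads$i5_well)]
  umi_obs <- mol$umi[midx]

  e <- config$index_error_rate
  m7 <- mutate_bases(i7_obs, e)
  m5 <- mutate_bases(i5_obs, e)
  mu <- mutate_bases(umi_obs, e)

  qual_str <- strrep(phred_char(30L), frag_len)
  out_reads <- data.table(
    read_id = reads$read_id,
    i7_obs = m7$seqs, i5_obs = m5$seqs, umi_obs = mu$seqs,
    insert = amp$insert, qual = qual_str,
    ref_start = mol$ref_start[midx], strand = mol$strand[midx],
    mapq = 60L
  )
  truth <- data.table(
    read_id = reads$read_id,
    true_sample = mol$sample[midx], true_well = mol$well[midx],
    molecule_id = midx, umi_true = umi_obs,
    ref_start = mol$ref_start[midx], strand = mol$strand[midx],
    contaminated_i7_arm = mol$i7_well[midx] != mol$well[midx],
    contaminated_i5_arm = mol$i5_well[midx] != mol$well[midx],
    hopped_i7 = hopped_i7, hopped_i5 = hopped_i5,
    err_i7 = m7$changed, err_i5 = m5$changed, err_umi = mu$changed,
    index_seq_error = m7$changed | m5$changed | mu$changed,
    oxo_misread = amp$oxo_shown,
    oxo_pos = mol$ref_start[midx] + mol$oxo_offset[midx] - 1L
  )
  structure(list(reads = out_reads, truth = truth, reference = reference,
                 plate = plate, sheet = sheet, config = config),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment> %d reads, %d samples, scheme=%s, seed=%d\n",
    nrow(x$reads), nrow(x$sheet), x$plate$scheme, x$config$seed))
  invisible(x)
}

#' Write a simulated experiment as a four-file FASTQ set
#'
#' Emits `<prefix>_R1.fastq` / `_R2.fastq` (insert, forward and
#' reverse-complement), `_I1.fastq` (i7 index followed by the UMI when the
#' plate carries UMIs) and `_I2.fastq` (i5 index), with identical read ids
#' in identical order across files and Phred+33 qualities.
#'
#' @param sim a `sim_experiment`.
#' @param prefix output path prefix.
#' @param compress write gzipped files with `.gz` extension.
#' @return named character vector of the four paths, invisibly.
#' @export
write_fastq <- function(sim, prefix, compress = FALSE) {
  reads <- sim$reads
  ids <- paste0("read", reads$read_id)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2", "_I1", "_I2"), ext)
  names(paths) <- c("R1", "R2", "I1", "I2")
  wr <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::PhredQuality(quals)
    qs <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(qs, path, compress = compress)
  }
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$insert)))
  iq30 <- strrep(phred_char(30L), nchar(reads$i7_obs[1]) +
                   nchar(reads$umi_obs[1]))
  iq30_i5 <- strrep(phred_char(30L), nchar(reads$i5_obs[1]))
  wr(reads$insert, reads$qual, paths["R1"])
  wr(r2, reads$qual, paths["R2"])
  wr(paste0(reads$i7_obs, reads$umi_obs), iq30, paths["I1"])
  wr(reads$i5_obs, iq30_i5, paths["I2"])
  invisible(paths)
}

#' Read a four-file FASTQ set for demultiplexing
#'
#' @param prefix path prefix as used by [write_fastq()].
#' @param umi_length trailing bases of I1 to split off as the UMI (0 for
#'   combinatorial libraries).
#' @param compress files carry a `.gz` extension.
#' @return data.table with columns read_id, i7_obs, i5_obs, umi_obs,
#'   insert, qual.
#' @export
read_fastq_set <- function(prefix, umi_length = 0L, compress = FALSE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  rd <- function(tag) {
    # the reader warns about dropped metadata columns when re-attaching
    # names; harmless here
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(paste0(prefix, "_", tag,
                                                       ext)))
  }
  r1 <- rd("R1"); i1 <- rd("I1"); i2 <- rd("I2")
  ids <- names(r1)
  if (!identical(ids, names(i1)) || !identical(ids, names(i2))) {
    stop("read ids differ across FASTQ files")
  }
  i1s <- as.character(i1)
  L1 <- nchar(i1s[1])
  i7 <- substr(i1s, 1L, L1 - umi_length)
  umi <- if (umi_length > 0) substr(i1s, L1 - umi_length + 1L, L1) else
    rep.int("", length(i1s))
  data.table(read_id = ids, i7_obs = i7, i5_obs = as.character(i2),
             umi_obs = umi, insert = as.character(r1),
             qual = as.character(Biostrings::quality(r1)))
}

#' Write the per-read truth table as TSV
#'
#' One row per emitted read; event tags are collapsed into a comma-joined
#' `event_tags` column. A header comment records the seed.
#'
#' @param sim a `sim_experiment`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_truth_table <- function(sim, path) {
  tr <- copy(sim$truth)
  tags <- c("contaminated_i7_arm", "contaminated_i5_arm", "hopped_i7",
            "hopped_i5", "index_seq_error", "oxo_misread")
  tagm <- as.matrix(tr[, tags, with = FALSE])
  joined <- apply(tagm, 1L, function(r) paste(tags[r], collapse = ","))
  out <- data.table(read_id = paste0("read", tr$read_id),
                    true_sample = tr$true_sample,
                    molecule_id = tr$molecule_id,
                    event_tags = joined,
                    ref_start = tr$ref_start, strand = tr$strand,
                    umi = tr$umi_true)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#seed=%d", sim$config$seed), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
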