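#' Simulation configuration
#'
#' Parameters of the synthetic exome cohort generator. Counts are drawn
#' negative-binomially around a log-normal per-target baseline scaled by a
#' per-sample batch factor — deliberately a different family from the
#' caller's beta-binomial, so tests probe robustness rather than
#' self-confirmation.
#'
#' @param n_controls Number of samples in the cohort.
#' @param n_targets Total targets, split evenly across chromosomes.
#' @param chromosomes Number of synthetic chromosomes (`chr1`, `chr2`, ...).
#' @param mean_depth Mean fragments per target for a diploid sample.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param batch_factors Multiplicative per-batch depth effects; samples
#'   are assigned to batches round-robin.
#' @param low_mappability_fraction Fraction of targets assigned decoy
#'   (low-uniqueness) mappability.
#' @param decoy_noise_mean Mean of the extra mis-mapping count added at
#'   decoy targets for affected samples. The default, twice the target
#'   depth, reflects a near-identical homolog elsewhere in the genome
#'   donating its own reads to the decoy locus.
#' @param decoy_sample_fraction Fraction of samples carrying the shared
#'   mis-mapping noise at each decoy target.
#' @param escaped_decoy_fraction Fraction of decoy targets whose mean
#'   mappability stays just above the 0.75 exclusion threshold, so they
#'   escape the filter while still carrying mis-mapping noise — the
#'   mechanism behind recurrent artifact calls that survive filtering.
#' @param events Spiked CNVs: a data frame with columns `sample`,
#'   `start_target`, `end_target` (1-based global target indices,
#'   inclusive) and `copy_number` in {0, 1, 3, 4}.
#' @param seed Master seed; all randomness flows from it.
#' @param target_width,target_gap Target geometry in bp.
#' @param sdlog Log-normal sd of the per-target baseline depth.
#' @param probe_spacing Synthetic SNP-array probe spacing in bp.
#' @return A list of class `exocnv_simconfig`.
#' @export
simulation_config <- function(n_controls = 30L, n_targets = 600L,
                              chromosomes = 2L, mean_depth = 200,
                              dispersion = 100, batch_factors = c(1, 1.15, 0.85),
                              low_mappability_fraction = 0.05,
                              decoy_noise_mean = NULL,
                              decoy_sample_fraction = 0.5,
                              escaped_decoy_fraction = 0.25,
                              events = NULL, seed = 1L,
                              target_width = 150L, target_gap = 850L,
                              sdlog = 1.0, probe_spacing = 1000L) {
  stopifnot(n_controls >= 1, n_targets >= 1, chromosomes >= 1,
            mean_depth > 0, dispersion > 0,
            low_mappability_fraction >= 0, low_mappability_fraction <= 1)
  if (!is.null(events)) {
    events <- as_tibble(events)
    stopifnot(all(c("sample", "start_target", "end_target", "copy_number")
                  %in% names(events)))
    if (any(events$start_target < 1 | events$end_target > n_targets |
              events$start_target > events$end_target)) {
      abort("event target range outside target bounds", class = "exocnv_state_error")
    }
    if (!all(events$copy_number %in% c(0L, 1L, 3L, 4L))) {
      abort("event copy_number must be in {0,1,3,4}", class = "exocnv_state_error")
    }
  }
  structure(list(
    n_controls = as.integer(n_controls), n_targets = as.integer(n_targets),
    chromosomes = as.integer(chromosomes), mean_depth = mean_depth,
    dispersion = dispersion, batch_factors = batch_factors,
    low_mappability_fraction = low_mappability_fraction,
    decoy_noise_mean = decoy_noise_mean %||% (2 * mean_depth),
    decoy_sample_fraction = decoy_sample_fraction,
    escaped_decoy_fraction = escaped_decoy_fraction,
    events = events, seed = as.integer(seed),
    target_width = as.integer(target_width), target_gap = as.integer(target_gap),
    sdlog = sdlog, probe_spacing = as.integer(probe_spacing)
  ), class = "exocnv_simconfig")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sim_targets <- function(cfg) {
  per_chrom <- rep(cfg$n_targets %/% cfg$chromosomes, cfg$chromosomes)
  per_chrom[seq_len(cfg$n_targets %% cfg$chromosomes)] <-
    per_chrom[seq_len(cfg$n_targets %% cfg$chromosomes)] + 1L
  pitch <- cfg$target_width + cfg$target_gap
  bind_rows(lapply(seq_len(cfg$chromosomes), function(k) {
    n <- per_chrom[k]
    start <- 1000L + (seq_len(n) - 1L) * pitch
    tibble(chrom = sprintf("chr%d", k), start = start,
           end = start + cfg$target_width,
           gene = sprintf("G%d", ((seq_len(n) - 1L) %/% 10L) + 1L),
           target_id = sprintf("chr%d_t%04d", k, seq_len(n)))
  }))
}

#' Simulate a synthetic exome cohort
#'
#' Generates a target set, a count matrix with batch structure, decoy
#' (low-mappability) targets carrying shared mis-mapping noise, and the
#' spiked CNV events from the configuration. Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg An [simulation_config()] object.
#' @return A list with `counts` (count-matrix tibble), `targets` (target
#'   tibble, with a logical `decoy` column), `truth` (the event table with
#'   genomic coordinates added), `baseline` (the drawn per-target mean
#'   depths) and `sample_factors` (per-sample batch multipliers).
#' @export
simulate_cohort <- function(cfg) {
  with_local_seed(cfg$seed, {
    targets <- sim_targets(cfg)
    targets$decoy <- FALSE
    targets$escaped <- FALSE
    n_decoy <- round(cfg$low_mappability_fraction * cfg$n_targets)
    if (n_decoy > 0) {
      decoy_idx <- sample.int(cfg$n_targets, n_decoy)
      targets$decoy[decoy_idx] <- TRUE
      n_escaped <- round(cfg$escaped_decoy_fraction * n_decoy)
      if (n_escaped > 0) {
        targets$escaped[sample(decoy_idx, n_escaped)] <- TRUE
      }
    }
    samples <- sprintf("S%03d", seq_len(cfg$n_controls))
    batch <- rep_len(seq_along(cfg$batch_factors), cfg$n_controls)
    s_j <- cfg$batch_factors[batch]
    mu_i <- stats::rlnorm(cfg$n_targets,
                          meanlog = log(cfg$mean_depth) - cfg$sdlog^2 / 2,
                          sdlog = cfg$sdlog)
    cn <- matrix(2, nrow = cfg$n_targets, ncol = cfg$n_controls,
                 dimnames = list(NULL, samples))
    if (!is.null(cfg$events)) {
      for (r in seq_len(nrow(cfg$events))) {
        ev <- cfg$events[r, ]
        if (!ev$sample %in% samples) {
          abort(paste0("event sample not in cohort: ", ev$sample),
                class = "exocnv_state_error")
        }
        if (targets$chrom[ev$start_target] != targets$chrom[ev$end_target]) {
          abort(sprintf("event %d spans a chromosome boundary (targets %d-%d)",
                        r, ev$start_target, ev$end_target),
                class = "exocnv_state_error")
        }
        cn[ev$start_target:ev$end_target, ev$sample] <- ev$copy_number
      }
    }
    mean_mat <- outer(mu_i, s_j) * cn / 2
    counts_mat <- matrix(
      rnbinom(length(mean_mat), size = cfg$dispersion, mu = mean_mat),
      nrow = cfg$n_targets, dimnames = list(NULL, samples)
    )
    if (any(targets$decoy) && cfg$decoy_noise_mean > 0) {
      for (i in which(targets$decoy)) {
        affected <- runif(cfg$n_controls) < cfg$decoy_sample_fraction
        if (any(affected)) {
          counts_mat[i, affected] <- counts_mat[i, affected] +
            rnbinom(sum(affected), size = cfg$dispersion,
                    mu = cfg$decoy_noise_mean)
        }
      }
    }
    counts <- tibble(target_id = targets$target_id)
    for (s in samples) counts[[s]] <- as.integer(counts_mat[, s])
    truth <- if (is.null(cfg$events)) {
      tibble(sample = character(), start_target = integer(),
             end_target = integer(), copy_number = integer(),
             chrom = character(), start = integer(), end = integer())
    } else {
      mutate(cfg$events,
             chrom = targets$chrom[.data$start_target],
             start = targets$start[.data$start_target],
             end = targets$end[.data$end_target])
    }
    list(counts = counts, targets = new_targets(targets), truth = truth,
         baseline = tibble(target_id = targets$target_id, mu = mu_i,
                           decoy = targets$decoy,
                           escaped = targets$escaped),
         sample_factors = tibble(sample_id = samples, factor = s_j))
  })
}

#' Simulate a base-level mappability track for a target set
#'
#' Decoy targets receive low base-level uniqueness (two half-exon
#' intervals at 0.1 and 0.5, mean 0.3, below the 0.75 exclusion
#' threshold), except "escaped" decoys, whose two intervals score 0.7 and
#' 0.9 (mean 0.8) so the filter keeps them despite the mis-mapping noise
#' they carry; all other targets score 1.0. Inter-target space is left
#' uncovered. The exact per-target means are attached as the
#' `"target_means"` attribute.
#'
#' @param targets A target tibble with a logical `decoy` column (as
#'   produced by [simulate_cohort()]).
#' @return A mappability-track tibble.
#' @export
simulate_mappability_track <- function(targets) {
  if (!"decoy" %in% names(targets)) {
    abort("targets lack a decoy column; use simulate_cohort() output",
          class = "exocnv_state_error")
  }
  escaped <- if ("escaped" %in% names(targets)) targets$escaped
    else rep(FALSE, nrow(targets))
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    if (targets$decoy[i]) {
      mid <- targets$start[i] + (targets$end[i] - targets$start[i]) %/% 2L
      sc <- if (escaped[i]) c(0.7, 0.9) else c(0.1, 0.5)
      tibble(chrom = targets$chrom[i],
             start = c(targets$start[i], mid),
             end = c(mid, targets$end[i]),
             score = sc)
    } else {
      tibble(chrom = targets$chrom[i], start = targets$start[i],
             end = targets$end[i], score = 1.0)
    }
  })
  track <- mappability_track(bind_rows(rows))
  means <- tibble(target_id = targets$target_id,
                  mean = map_dbl(seq_len(nrow(targets)), function(i) {
                    exon_mean_mappability(targets$chrom[i], targets$start[i],
                                          targets$end[i], track)
                  }))
  attr(track, "target_means") <- means
  track
}

#' Simulate SNP-array truth records for spiked events
#'
#' Places synthetic array probes at fixed spacing along each chromosome
#' and converts each spiked event into an array-style CNV record with its
#' probe count and zygosity state (copy number 0 = homozygous deletion,
#' 1 = heterozygous deletion, 3 = duplication, 4 = triplication).
#' Coordinates in the returned records are 1-based inclusive, matching
#' array export conventions.
#'
#' @param truth Event table from [simulate_cohort()] (`$truth`).
#' @param targets The simulated target tibble.
#' @param probe_spacing Probe pitch in bp.
#' @return A list with `array_cnvs` (tibble: sample_id, chrom, start, end,
#'   state, n_probes, clinically_reported) and `probes` (tibble: chrom,
#'   pos).
#' @export
simulate_array_truth <- function(truth, targets, probe_spacing = 1000L) {
  probes <- bind_rows(lapply(unique(targets$chrom), function(ch) {
    lim <- range(targets$start[targets$chrom == ch],
                 targets$end[targets$chrom == ch])
    tibble(chrom = ch, pos = seq(500L, lim[2] + probe_spacing,
                                 by = probe_spacing))
  }))
  state_map <- c(`0` = "hom_del", `1` = "het_del", `3` = "dup", `4` = "trip")
  array_cnvs <- tibble(
    sample_id = truth$sample,
    chrom = truth$chrom,
    start = truth$start + 1L,
    end = truth$end,
    state = unname(state_map[as.character(truth$copy_number)]),
    n_probes = map_int(seq_len(nrow(truth)), function(r) {
      sum(probes$chrom == truth$chrom[r] &
            probes$pos >= truth$start[r] + 1L & probes$pos <= truth$end[r])
    }),
    clinically_reported = FALSE
  )
  list(array_cnvs = array_cnvs, probes = probes)
}

#' Write a small synthetic SAM file over a target set
#'
#' Emits single-end reads placed inside chosen targets on a toy contig
#' header, so the alignment-counting path has a plain-text fixture.
#'
#' @param targets Target tibble (defines the contigs and coordinates).
#' @param reads A tibble with columns `target` (row index into `targets`),
#'   `n` (reads to emit), and optional `mapq` (default 60), `dup`
#'   (duplicate-flag, default FALSE).
#' @param path Output SAM path.
#' @param read_length Read length in bp.
#' @return `path`, invisibly.
#' @export
simulate_sam <- function(targets, reads, path, read_length = 100L) {
  reads <- as_tibble(reads)
  if (!"mapq" %in% names(reads)) reads$mapq <- 60L
  if (!"dup" %in% names(reads)) reads$dup <- FALSE
  chrom_len <- targets |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$end) + 10000L)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom_len$chrom, chrom_len$len))
  recs <- character(0)
  k <- 0L
  for (r in seq_len(nrow(reads))) {
    tg <- targets[reads$target[r], ]
    for (j in seq_len(reads$n[r])) {
      k <- k + 1L
      pos <- tg$start + 1L + ((j - 1L) %% max(1L, tg$end - tg$start - read_length))
      flag <- if (reads$dup[r]) 1024L else 0L
      recs <- c(recs, sprintf(
        "read%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
        k, flag, tg$chrom, pos, reads$mapq[r], read_length,
        paste(rep("A", read_length), collapse = ""),
        paste(rep("I", read_length), collapse = "")))
    }
  }
  ord <- order(map_chr(strsplit(recs, "\t"), 3L),
               as.integer(map_chr(strsplit(recs, "\t"), 4L)))
  writeLines(c(hdr, recs[ord]), path)
  invisible(path)
}

#' Lay out non-overlapping spike-in events across a cohort
#'
#' Deterministically places `n_events` CNV events of `min_len` to
#' `max_len` targets, assigned round-robin to samples and strided across
#' the target space so no two events in one sample share targets and no
#' event crosses a chromosome boundary.
#'
#' @param n_events Number of events.
#' @param n_samples Cohort size (samples named `S001`, ...).
#' @param n_targets,chromosomes Target-space geometry (must match the
#'   [simulation_config()] the events are used with).
#' @param copy_number Copy number of every event (default 1, heterozygous
#'   deletion).
#' @param min_len,max_len Event lengths in targets; lengths cycle through
#'   the range.
#' @return An event tibble for [simulation_config()].
#' @export
spike_events <- function(n_events, n_samples, n_targets, chromosomes = 1L,
                         copy_number = 1L, min_len = 3L, max_len = 5L) {
  per_chrom <- n_targets %/% chromosomes
  stride <- max((n_targets - 20L) %/% n_events, max_len + 2L)
  lens <- min_len + (seq_len(n_events) - 1L) %% (max_len - min_len + 1L)
  start <- 10L + (seq_len(n_events) - 1L) * stride
  end <- start + lens - 1L
  # shift events off chromosome boundaries
  cross <- ((start - 1L) %/% per_chrom) != ((end - 1L) %/% per_chrom)
  start[cross] <- ((end[cross] - 1L) %/% per_chrom) * per_chrom + 1L
  end[cross] <- start[cross] + lens[cross] - 1L
  if (any(end > n_targets)) {
    abort("event layout exceeds target space; reduce n_events or lengths",
          class = "exocnv_state_error")
  }
  tibble(sample = sprintf("S%03d", (seq_len(n_events) - 1L) %% n_samples + 1L),
         start_target = start, end_target = end,
         copy_number = as.integer(copy_number))
}

#' Find callable spike-in windows in a simulated cohort
#'
#' Returns start indices (global target numbering) of runs of `len`
#' consecutive targets on one chromosome that are non-decoy and have
#' baseline depth at least `min_depth`. Spiked events placed on such
#' windows are observable by read depth, mirroring how array-confirmed
#' truth CNVs necessarily sit on assayable territory.
#'
#' @param sim A [simulate_cohort()] result.
#' @param len Window length in targets.
#' @param min_depth Minimum baseline mean depth per target.
#' @return Integer vector of window start indices (possibly empty).
#' @export
callable_windows <- function(sim, len = 5L, min_depth = 100) {
  ok <- !sim$baseline$decoy & sim$baseline$mu >= min_depth
  chrom <- sim$targets$chrom
  n <- length(ok)
  if (n < len) return(integer(0))
  which(vapply(seq_len(n - len + 1L), function(i) {
    all(ok[i:(i + len - 1L)]) && chrom[i] == chrom[i + len - 1L]
  }, logical(1)))
}
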