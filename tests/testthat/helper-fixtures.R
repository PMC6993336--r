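# Shared fixture builders, all programmatic.

write_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

toy_targets <- function(n = 5, chrom = "chr1", width = 100L, gap = 400L,
                        included = TRUE) {
  start <- 1000L + (seq_len(n) - 1L) * (width + gap)
  tibble::tibble(chrom = chrom, start = start, end = start + width,
                 gene = "G", target_id = sprintf("%s_t%03d", chrom, seq_len(n)),
                 mean_mappability = 1, included = included)
}

# Reference model built directly (bypasses selection) for emission /
# segmentation unit tests.
make_reference <- function(aggregate, p, phi = 0) {
  structure(list(selected_controls = "ctrl", aggregate = aggregate,
                 p = rep(p, length(aggregate))[seq_along(aggregate)],
                 r2 = 1, phi = phi),
            class = "exocnv_reference")
}

# Standard small cohort with one spiked het deletion over targets 40-44.
spiked_cohort <- function(seed = 42, n_controls = 30, n_targets = 200,
                          events = tibble::tibble(sample = "S005",
                                                  start_target = 40L,
                                                  end_target = 44L,
                                                  copy_number = 1L)) {
  cfg <- simulation_config(n_controls = n_controls, n_targets = n_targets,
                           chromosomes = 2, mean_depth = 200,
                           events = events, seed = seed)
  sim <- simulate_cohort(cfg)
  track <- simulate_mappability_track(sim$targets)
  targets <- filter_by_mappability(annotate_mappability(sim$targets, track))
  list(sim = sim, targets = targets, track = track)
}

random_track <- function(seed, chrom = "chr1", n_iv = 8, span = 1000L) {
  set.seed(seed)
  cuts <- sort(sample(seq_len(span - 1), n_iv - 1))
  bounds <- c(0L, cuts, span)
  tibble::tibble(chrom = chrom, start = bounds[-length(bounds)],
                 end = bounds[-1], score = round(runif(n_iv), 3))
}

# Deepest callable windows for spike placement: an 8-target window for a
# duplication (1.5x shifts need more depth than 0.5x), and a disjoint
# 5-target window for a deletion.
pick_spike_windows <- function(sim0) {
  wdup <- callable_windows(sim0, 8L, 0)
  ddep <- sapply(wdup, function(i) sum(sim0$baseline$mu[i:(i + 7)]))
  w_dup <- wdup[order(ddep, decreasing = TRUE)][1]
  wdel <- callable_windows(sim0, 5L, 0)
  wdel <- wdel[wdel + 4 < w_dup | wdel > w_dup + 7]
  dd <- sapply(wdel, function(i) sum(sim0$baseline$mu[i:(i + 4)]))
  c(del = wdel[order(dd, decreasing = TRUE)][1], dup = w_dup)
}
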