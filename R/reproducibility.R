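#' Iteration configuration for control resampling
#'
#' @param n_iterations Number of recalling iterations (default 1000, the
#'   scale used for full cohorts; tests use fewer).
#' @param subset_size Controls drawn per iteration (default 200).
#' @param master_seed Master seed; every iteration's draw derives from it.
#' @return A list of class `exocnv_iterconfig`.
#' @export
iteration_config <- function(n_iterations = 1000L, subset_size = 200L,
                             master_seed = 1L) {
  stopifnot(n_iterations >= 1, subset_size >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 subset_size = as.integer(subset_size),
                 master_seed = as.integer(master_seed)),
            class = "exocnv_iterconfig")
}

#' Deterministic child seed for one (sample, iteration) pair
#'
#' Counter-based integer mix of the master seed, the sample id's bytes and
#' the iteration number, kept in `[0, 2^31)`. Per-sample runs can thus be
#' parallelised or resumed without changing any draw.
#'
#' @param master_seed Integer master seed.
#' @param sample_id Sample label.
#' @param iteration Iteration counter (1-based).
#' @return An integer seed.
#' @export
child_seed <- function(master_seed, sample_id, iteration) {
  m <- 2147483647
  h <- (abs(as.numeric(master_seed)) %% m)
  for (b in utf8ToInt(as.character(sample_id))) {
    h <- (h * 69069 + b) %% m
  }
  h <- (h * 69069 + as.numeric(iteration)) %% m
  h <- (h * 69069 + 1) %% m
  as.integer(h)
}

call_overlaps_targets <- function(chrom, start, end, targets) {
  which(targets$included & targets$chrom == chrom &
          targets$start < end & targets$end > start)
}

#' Do two calls hit the same CNV region?
#'
#' Two calls are the same region if they share at least one included
#' target and have the same CNV type. Target sharing (rather than
#' coordinate equality) is robust to boundary jitter between iterations.
#'
#' @param a,b Single-row call tibbles on the same sample's target set.
#' @param targets The filtered target tibble.
#' @return Logical.
#' @export
same_region <- function(a, b, targets) {
  if (a$cnv_type != b$cnv_type || a$chrom != b$chrom) return(FALSE)
  ta <- call_overlaps_targets(a$chrom, a$start, a$end, targets)
  tb <- call_overlaps_targets(b$chrom, b$start, b$end, targets)
  length(intersect(ta, tb)) > 0L
}

#' Re-call one sample against random control subsets
#'
#' Runs [call_sample()] `n_iterations` times, each against a fresh subset
#' of `subset_size` controls drawn uniformly without replacement from the
#' pool (every sample except the test). Draws use deterministic child
#' seeds from [child_seed()], so results are fully reproducible given the
#' master seed. Iterations failing correlation QC contribute an empty call
#' set and still count in the reproducibility denominator.
#'
#' @param test_id Test sample id.
#' @param counts Count-matrix tibble.
#' @param targets Filtered target tibble.
#' @param params An [caller_params()] object.
#' @param cfg An [iteration_config()] object.
#' @return A list of per-iteration call tibbles (length `n_iterations`),
#'   with per-iteration QC status in the `"statuses"` attribute.
#' @export
run_iterations <- function(test_id, counts, targets, params = caller_params(),
                           cfg = iteration_config()) {
  pool <- setdiff(count_samples(counts), test_id)
  if (length(pool) < cfg$subset_size) {
    abort(sprintf("control pool (%d) smaller than subset_size (%d); maximum feasible subset_size is %d",
                  length(pool), cfg$subset_size, length(pool)),
          class = "exocnv_state_error")
  }
  statuses <- character(cfg$n_iterations)
  out <- vector("list", cfg$n_iterations)
  for (k in seq_len(cfg$n_iterations)) {
    seed_k <- child_seed(cfg$master_seed, test_id, k)
    subset <- with_local_seed(seed_k, sample(pool, cfg$subset_size))
    calls <- call_sample(test_id, counts, targets, params, pool_ids = subset)
    statuses[k] <- attr(calls, "status")
    out[[k]] <- calls
  }
  attr(out, "statuses") <- statuses
  out
}

#' Score how reproducibly each initial call recurs
#'
#' For each call from the initial (full-pool) run, counts the iterations
#' containing at least one call in the same region with the same type, and
#' flags regions that were called as both a deletion and a duplication
#' across iterations (`type_consistent = FALSE`).
#'
#' @param initial_calls Call tibble from the initial run.
#' @param iteration_callsets List of per-iteration call tibbles from
#'   [run_iterations()].
#' @param targets Filtered target tibble.
#' @return `initial_calls` with `n_detected`, `n_iterations` and
#'   `type_consistent` columns appended.
#' @export
score_reproducibility <- function(initial_calls, iteration_callsets, targets) {
  n_iter <- length(iteration_callsets)
  n_detected <- integer(nrow(initial_calls))
  type_consistent <- rep(TRUE, nrow(initial_calls))
  if (nrow(initial_calls) > 0L) {
    ti <- lapply(seq_len(nrow(initial_calls)), function(i) {
      call_overlaps_targets(initial_calls$chrom[i], initial_calls$start[i],
                            initial_calls$end[i], targets)
    })
    for (it in iteration_callsets) {
      if (nrow(it) == 0L) next
      tj <- lapply(seq_len(nrow(it)), function(j) {
        call_overlaps_targets(it$chrom[j], it$start[j], it$end[j], targets)
      })
      for (i in seq_len(nrow(initial_calls))) {
        share <- map_lgl(seq_len(nrow(it)), function(j) {
          it$chrom[j] == initial_calls$chrom[i] &&
            length(intersect(ti[[i]], tj[[j]])) > 0L
        })
        same <- share & it$cnv_type == initial_calls$cnv_type[i]
        if (any(same)) n_detected[i] <- n_detected[i] + 1L
        if (any(share & it$cnv_type != initial_calls$cnv_type[i])) {
          type_consistent[i] <- FALSE
        }
      }
    }
  }
  mutate(initial_calls, n_detected = n_detected, n_iterations = n_iter,
         type_consistent = type_consistent)
}

#' Partition scored calls by reproducibility
#'
#' Splits scored calls at a detection-count threshold into high- and
#' low-confidence sets, each stably ordered by descending detection count
#' then descending Bayes factor.
#'
#' @param scores Scored call tibble from [score_reproducibility()].
#' @param threshold Minimum detections for high confidence.
#' @return A list with `high_confidence` and `low_confidence` tibbles.
#' @export
rank_calls <- function(scores, threshold) {
  if (nrow(scores) > 0L && threshold > scores$n_iterations[1]) {
    abort("threshold exceeds n_iterations", class = "exocnv_state_error")
  }
  ord <- arrange(scores, dplyr::desc(.data$n_detected), dplyr::desc(.data$bf))
  list(high_confidence = filter(ord, .data$n_detected >= threshold),
       low_confidence = filter(ord, .data$n_detected < threshold))
}

#' Summarise a reproducibility score table
#'
#' @param scores Scored call tibble.
#' @return One-row tibble with the number of calls, the number detected in
#'   every iteration, and the fully-reproducible percentage (nearest
#'   integer, with the exact proportion retained).
#' @export
reproducibility_summary <- function(scores) {
  n_full <- sum(scores$n_detected == scores$n_iterations)
  prop <- if (nrow(scores) > 0) n_full / nrow(scores) else NA_real_
  tibble(n_calls = nrow(scores), n_fully_reproducible = n_full,
         prop_fully_reproducible = prop,
         pct_fully_reproducible = round(100 * prop))
}

#' Write a reproducibility score table as TSV
#' @param scores Scored call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- mutate(scores, start = .data$start + 1L)
  readr::write_tsv(out, path)
  invisible(path)
}
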