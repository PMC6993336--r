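#' Caller parameters
#'
#' Tunable parameters of the three-state read-depth HMM.
#'
#' @param transition_prob Probability of entering a CNV state between
#'   adjacent targets (default 1e-4). Transitions are distance-independent.
#' @param expected_cnv_targets Expected number of targets spanned by a CNV
#'   (default 5); the CNV-state self-transition is `1 - 1/expected_cnv_targets`.
#' @param phi Beta-binomial overdispersion. `NULL` (default) means fit it
#'   per sample by maximum likelihood; 0 reduces the emissions to binomial.
#' @param min_bf Minimum log10 Bayes factor for a call to be reported
#'   (default 0: no filter).
#' @param qc_r2 Minimum squared correlation between a test sample and its
#'   aggregate reference panel (default 0.97); samples below it are
#'   rejected rather than called.
#' @param max_panel Maximum number of controls in the reference panel
#'   (default 12).
#' @param min_panel Minimum number of controls aggregated when calling
#'   (default 3; capped at the pool size). A single-control reference is
#'   too noisy for per-target expectations, so the caller widens the
#'   panel even when a smaller prefix correlates marginally better.
#' @return A list of class `exocnv_params`.
#' @export
caller_params <- function(transition_prob = 1e-4, expected_cnv_targets = 5L,
                          phi = NULL, min_bf = 0, qc_r2 = 0.97,
                          max_panel = 12L, min_panel = 3L) {
  stopifnot(transition_prob > 0, transition_prob < 1,
            expected_cnv_targets >= 1, is.null(phi) || phi >= 0,
            max_panel >= 1)
  if (transition_prob >= 1 / expected_cnv_targets) {
    abort("transition_prob must be smaller than 1/expected_cnv_targets",
          class = "exocnv_state_error")
  }
  structure(list(transition_prob = transition_prob,
                 expected_cnv_targets = as.integer(expected_cnv_targets),
                 phi = phi, min_bf = min_bf, qc_r2 = qc_r2,
                 max_panel = as.integer(max_panel),
                 min_panel = as.integer(min_panel)),
            class = "exocnv_params")
}

#' Beta-binomial log probability mass
#'
#' Parameterised by mean `p` and overdispersion `phi` with shape
#' `alpha = p/phi`, `beta = (1-p)/phi`, so `phi -> 0` recovers the
#' binomial exactly (and `phi = 0` dispatches to [stats::dbinom()]).
#' @noRd
bb_logpmf <- function(y, n, p, phi) {
  if (phi <= 0) return(dbinom(y, n, p, log = TRUE))
  a <- p / phi
  b <- (1 - p) / phi
  lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
}

state_q <- c(CN1 = 0.5, CN2 = 1, CN3 = 1.5)

#' Emission log-likelihood of a copy-number state
#'
#' The test sample's count `y` out of the test + reference total `n` is
#' modelled as beta-binomial with expected proportion `p` under the
#' diploid state. Copy number `c` rescales the odds by `q = c/2`:
#' `p' = q*p / (q*p + 1 - p)`, so a heterozygous deletion halves and a
#' duplication multiplies by 1.5 the expected test share.
#'
#' @param y Test count(s) per target.
#' @param n Test + reference total(s) per target.
#' @param p Expected test proportion(s) under the diploid state, in (0,1).
#' @param phi Overdispersion, `>= 0` (0 = binomial).
#' @param state One of `"CN1"`, `"CN2"`, `"CN3"` (deletion / normal /
#'   duplication).
#' @return Natural-log likelihood(s), finite for all valid inputs.
#' @export
emission_loglik <- function(y, n, p, phi, state) {
  if (any(y > n)) abort("count y exceeds total n", class = "exocnv_state_error")
  if (any(p <= 0 | p >= 1)) abort("p must lie in (0,1)", class = "exocnv_state_error")
  q <- state_q[[match.arg(state, names(state_q))]]
  p2 <- q * p / (q * p + 1 - p)
  bb_logpmf(y, n, p2, phi)
}

#' Select a reference panel of correlated controls
#'
#' Controls are ranked by Pearson correlation of per-target counts with
#' the test sample and added greedily in rank order; the panel kept is the
#' rank prefix (of size at most `max_panel`) whose aggregate is most
#' correlated with the test sample, so one locally unhelpful control
#' cannot truncate an otherwise better panel. The
#' expected diploid test proportion is the ratio of total test to total
#' test + aggregate counts over informative targets; targets with zero
#' aggregate coverage are masked from segmentation.
#'
#' @param test Numeric vector of test counts over the included targets.
#' @param pool Count-matrix tibble (or numeric matrix) of control samples
#'   over the same targets; must not contain the test sample.
#' @param max_panel Maximum panel size (default 12).
#' @param min_panel Minimum panel size (default 1: the pure
#'   aggregate-correlation optimum; [call_sample()] raises it).
#' @return An object of class `exocnv_reference` with elements
#'   `selected_controls`, `aggregate`, `p` (per-target, NA where masked),
#'   `r2` (QC correlation of test vs aggregate) and `phi` (NA until
#'   fitted).
#' @export
select_reference <- function(test, pool, max_panel = 12L, min_panel = 1L) {
  if (is_tibble(pool) || is.data.frame(pool)) {
    pool <- as.matrix(pool[count_samples(as_tibble(pool))])
  }
  pool <- as.matrix(pool)
  if (ncol(pool) < 1L) abort("empty control pool", class = "exocnv_state_error")
  if (nrow(pool) != length(test)) {
    abort("pool and test differ in target count", class = "exocnv_state_error")
  }
  if (all(test == 0)) abort("all-zero test column", class = "exocnv_state_error")
  if (is.null(colnames(pool))) colnames(pool) <- paste0("control", seq_len(ncol(pool)))
  rho <- apply(pool, 2L, function(x) if (stats::sd(x) == 0) -Inf else cor(test, x))
  ord <- order(rho, decreasing = TRUE)
  kmax <- min(max_panel, ncol(pool))
  kmin <- min(max(1L, min_panel), kmax)
  run <- pool[, ord[1L]]
  best <- cor(test, run)
  best_k <- 1L
  if (kmax > 1L) {
    for (k in 2L:kmax) {
      run <- run + pool[, ord[k]]
      r <- cor(test, run)
      if (!is.na(r) && (r > best || k <= kmin)) {
        best <- r
        best_k <- k
      }
    }
  }
  selected <- ord[seq_len(best_k)]
  agg <- rowSums(pool[, selected, drop = FALSE])
  informative <- agg > 0
  p_hat <- sum(test[informative]) / (sum(test[informative]) + sum(agg[informative]))
  p <- ifelse(informative, p_hat, NA_real_)
  structure(list(selected_controls = colnames(pool)[selected],
                 aggregate = agg, p = p, r2 = best^2, phi = NA_real_),
            class = "exocnv_reference")
}

#' @export
print.exocnv_reference <- function(x, ...) {
  cat("<exocnv_reference>\n")
  cat("  controls:", length(x$selected_controls),
      paste0("(", paste(head(x$selected_controls, 5), collapse = ", "),
             if (length(x$selected_controls) > 5) ", ..." else "", ")"), "\n")
  cat(sprintf("  aggregate r2 vs test: %.4f\n", x$r2))
  cat(sprintf("  phi: %s\n", if (is.na(x$phi)) "unfitted" else format(x$phi)))
  invisible(x)
}

#' @export
tidy.exocnv_reference <- function(x, ...) {
  tibble(control = x$selected_controls, rank = seq_along(x$selected_controls))
}

#' @export
glance.exocnv_reference <- function(x, ...) {
  tibble(n_controls = length(x$selected_controls), r2 = x$r2, phi = x$phi,
         n_targets = length(x$aggregate), n_masked = sum(is.na(x$p)))
}

#' Fit the beta-binomial overdispersion
#'
#' Maximum-likelihood estimate of `phi` under the assumption that every
#' target is diploid in the test sample; used to calibrate emission
#' variance beyond binomial before segmentation. The fit is robust:
#' after an initial fit over all informative targets, targets whose
#' observed proportion deviates from expectation by more than `trim_z`
#' standard deviations under the fitted beta-binomial are excluded and
#' `phi` is refit. Such outlier loci are copy-number events or mapping
#' artifacts; letting them inflate `phi` would desensitise segmentation
#' everywhere else.
#'
#' @param test Test counts over the included targets.
#' @param reference An `exocnv_reference` from [select_reference()].
#' @param min_informative Minimum number of informative targets (test +
#'   reference total > 0) required for a stable fit (default 50).
#' @param trim_z Beta-binomial z-score beyond which a target is excluded
#'   from the refit (default 4).
#' @return The fitted `phi >= 0` (also written into a returned copy of
#'   `reference` by [call_sample()]).
#' @export
fit_overdispersion <- function(test, reference, min_informative = 50L,
                               trim_z = 4) {
  ok <- !is.na(reference$p)
  y <- test[ok]
  n <- test[ok] + reference$aggregate[ok]
  p <- reference$p[ok]
  keep <- n > 0
  if (sum(keep) < min_informative) {
    abort(sprintf("only %d informative targets; need >= %d for overdispersion fit",
                  sum(keep), min_informative),
          class = "exocnv_state_error")
  }
  y <- y[keep]; n <- n[keep]; p <- p[keep]
  fit1 <- function(y, n, p) {
    nll <- function(log10phi) -sum(bb_logpmf(y, n, p, 10^log10phi))
    opt <- optimize(nll, interval = c(-8, log10(0.5)))
    ll_binom <- sum(dbinom(y, n, p, log = TRUE))
    if (ll_binom >= -opt$objective) 0 else 10^opt$minimum
  }
  phi <- fit1(y, n, p)
  for (it in 1:2) {
    rho <- phi / (1 + phi)
    sd_bb <- sqrt(pmax(n * p * (1 - p) * (1 + (n - 1) * rho), 1e-12))
    inlier <- abs(y - n * p) / sd_bb <= trim_z
    if (sum(inlier) < min_informative || all(inlier)) break
    phi_new <- fit1(y[inlier], n[inlier], p[inlier])
    if (abs(phi_new - phi) <= 0.05 * max(phi, 1e-8)) {
      phi <- phi_new
      break
    }
    phi <- phi_new
  }
  phi
}

hmm_log_matrices <- function(params) {
  t <- params$transition_prob
  E <- params$expected_cnv_targets
  s <- 1 - 1 / E
  leave <- 1 / E - t
  A <- rbind(c(s, leave, t),
             c(t, 1 - 2 * t, t),
             c(t, leave, s))
  list(logA = log(A), logInit = log(c(t, 1 - 2 * t, t)))
}

#' Viterbi segmentation of a test sample
#'
#' Computes the maximum a posteriori state path of the three-state chain
#' (CN1 deletion / CN2 diploid / CN3 duplication) per chromosome and
#' converts maximal runs of non-diploid states into CNV calls. Ties in
#' path score resolve in favour of CN2, so degenerate input yields fewer
#' calls. Masked targets (zero aggregate coverage) are skipped and cannot
#' appear inside calls.
#'
#' @param test Test counts aligned to `targets`.
#' @param reference An `exocnv_reference` (with `phi` set, or supply
#'   `params$phi`).
#' @param targets Included target tibble aligned with `test`.
#' @param params An [caller_params()] object.
#' @param sample_id Sample label attached to emitted calls.
#' @return A list with `path` (per-target state, NA where masked) and
#'   `calls`, a tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `cnv_type`, `n_targets`, `bf` (log10 Bayes factor vs diploid) and
#'   `ratio` (observed/expected depth over the segment).
#' @export
viterbi_segment <- function(test, reference, targets, params = caller_params(),
                            sample_id = "test") {
  if (length(test) != nrow(targets) || length(reference$aggregate) != nrow(targets)) {
    abort("test, reference and targets must be aligned on the same target set",
          class = "exocnv_state_error")
  }
  phi <- params$phi %||% reference$phi
  if (is.na(phi)) abort("phi unset: fit_overdispersion() first or set params$phi",
                        class = "exocnv_state_error")
  mats <- hmm_log_matrices(params)
  states <- names(state_q)
  path <- rep(NA_character_, nrow(targets))
  calls <- list()
  for (chrom in unique(targets$chrom)) {
    idx <- which(targets$chrom == chrom & !is.na(reference$p) &
                   (test + reference$aggregate) > 0)
    if (length(idx) == 0L) next
    y <- test[idx]
    n <- test[idx] + reference$aggregate[idx]
    p <- reference$p[idx]
    em <- vapply(states, function(s) emission_loglik(y, n, p, phi, s),
                 numeric(length(idx)))
    em <- matrix(em, nrow = length(idx))
    sp <- viterbi_path(em, mats$logA, mats$logInit)
    path[idx] <- states[sp]
    calls[[chrom]] <- segment_calls(sp, idx, y, reference, targets, params,
                                    phi, sample_id)
  }
  calls <- bind_rows(calls)
  if (nrow(calls) > 0L) {
    calls <- arrange(filter(calls, .data$bf >= params$min_bf),
                     .data$chrom, .data$start)
  }
  list(path = path, calls = empty_calls_if_null(calls))
}

# Core dynamic program. Tie-break prefers CN2 (state 2), then CN1, then CN3.
viterbi_path <- function(em, logA, logInit) {
  Tn <- nrow(em)
  pref <- c(2L, 1L, 3L)
  v <- logInit + em[1L, ]
  bp <- matrix(NA_integer_, nrow = Tn, ncol = 3L)
  if (Tn > 1L) {
    for (t in 2L:Tn) {
      vnew <- numeric(3L)
      for (j in 1L:3L) {
        sc <- v + logA[, j]
        best <- pref[which.max(sc[pref])]
        bp[t, j] <- best
        vnew[j] <- sc[best] + em[t, j]
      }
      v <- vnew
    }
  }
  last <- pref[which.max(v[pref])]
  out <- integer(Tn)
  out[Tn] <- last
  if (Tn > 1L) for (t in Tn:2L) out[t - 1L] <- bp[t, out[t]]
  out
}

segment_calls <- function(sp, idx, y, reference, targets, params, phi, sample_id) {
  r <- rle(sp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    st <- r$values[k]
    if (st == 2L) next
    seg <- idx[starts[k]:ends[k]]
    state <- names(state_q)[st]
    bf <- bayes_factor(seg, state, test = NULL, reference, params,
                       y_seg = y[starts[k]:ends[k]], phi = phi)
    p_seg <- reference$p[seg]
    expected <- sum(p_seg / (1 - p_seg) * reference$aggregate[seg])
    out[[k]] <- tibble(
      sample_id = sample_id,
      chrom = targets$chrom[seg[1L]],
      start = targets$start[seg[1L]],
      end = targets$end[seg[length(seg)]],
      cnv_type = if (st == 1L) "deletion" else "duplication",
      n_targets = length(seg),
      bf = bf,
      ratio = sum(y[starts[k]:ends[k]]) / expected
    )
  }
  bind_rows(out)
}

empty_calls_if_null <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), cnv_type = character(),
                  n_targets = integer(), bf = numeric(), ratio = numeric()))
  }
  calls
}

#' Log10 Bayes factor of a called segment
#'
#' Sum over the segment's targets of the emission log10-likelihood
#' difference between the called state and the diploid state; positive
#' when the data support the call.
#'
#' @param segment Integer indices of the segment's targets (into the
#'   included target set).
#' @param state `"CN1"` or `"CN3"`.
#' @param test Test counts over the included targets (or pass `y_seg`).
#' @param reference An `exocnv_reference`.
#' @param params An [caller_params()] object (unused beyond validation;
#'   present for interface symmetry).
#' @param y_seg Optional pre-extracted test counts over the segment.
#' @param phi Overdispersion; defaults to `reference$phi`.
#' @return The log10 Bayes factor.
#' @export
bayes_factor <- function(segment, state, test, reference,
                         params = caller_params(), y_seg = NULL, phi = NULL) {
  if (length(segment) == 0L) abort("empty segment", class = "exocnv_state_error")
  phi <- phi %||% reference$phi
  y <- y_seg %||% test[segment]
  n <- y + reference$aggregate[segment]
  p <- reference$p[segment]
  sum(emission_loglik(y, n, p, phi, state) -
        emission_loglik(y, n, p, phi, "CN2")) / log(10)
}

#' Call CNVs for one sample against a control pool
#'
#' End-to-end single-sample calling: select a reference panel from the
#' pool, gate on correlation QC, fit the overdispersion, segment each
#' chromosome with the Viterbi HMM, and return coordinate-sorted calls.
#' Samples whose squared correlation with the aggregate reference falls
#' below `params$qc_r2` are rejected: the returned call tibble is empty
#' and carries `status = "qc_failed"`.
#'
#' @param test_id Sample id; must be a column of `counts`.
#' @param counts Count-matrix tibble over the full target set.
#' @param targets Target tibble with `included` filled
#'   ([filter_by_mappability()]); calling is restricted to included
#'   targets.
#' @param params An [caller_params()] object.
#' @param pool_ids Optional character vector restricting the control pool
#'   (e.g. a random subset); defaults to every other sample in `counts`.
#' @return A call tibble (see [viterbi_segment()]) with attributes
#'   `status` (`"ok"` or `"qc_failed"`), `r2`, `phi` and `panel`.
#' @export
call_sample <- function(test_id, counts, targets, params = caller_params(),
                        pool_ids = NULL) {
  samples <- count_samples(counts)
  if (!test_id %in% samples) {
    abort(paste0("unknown test sample: ", test_id), class = "exocnv_state_error")
  }
  pool_ids <- pool_ids %||% setdiff(samples, test_id)
  pool_ids <- setdiff(pool_ids, test_id)
  if (length(pool_ids) < 1L) abort("empty control pool", class = "exocnv_state_error")
  if (anyNA(targets$included)) {
    abort("targets not yet filtered; run filter_by_mappability()",
          class = "exocnv_state_error")
  }
  counts <- counts[match(targets$target_id, counts$target_id), , drop = FALSE]
  inc <- which(targets$included)
  tgt <- targets[inc, ]
  test <- counts[[test_id]][inc]
  pool <- counts[inc, pool_ids, drop = FALSE]
  ref <- select_reference(test, pool, max_panel = params$max_panel,
                          min_panel = params$min_panel)
  if (!passes_qc(ref$r2, params$qc_r2)) {
    out <- empty_calls_if_null(NULL)
    attr(out, "status") <- "qc_failed"
    attr(out, "r2") <- ref$r2
    attr(out, "phi") <- NA_real_
    attr(out, "panel") <- ref$selected_controls
    return(out)
  }
  ref$phi <- params$phi %||% fit_overdispersion(test, ref)
  res <- viterbi_segment(test, ref, tgt, params, sample_id = test_id)
  out <- res$calls
  attr(out, "status") <- "ok"
  attr(out, "r2") <- ref$r2
  attr(out, "phi") <- ref$phi
  attr(out, "panel") <- ref$selected_controls
  out
}

#' Write calls as TSV or VCF 4.2
#'
#' The TSV mirrors the call tibble (display coordinates are 1-based
#' inclusive). The VCF uses symbolic alleles `<DEL>`/`<DUP>` with `END`,
#' `BF` and `RATIO` in INFO.
#'
#' @param calls A call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- mutate(calls, start = .data$start + 1L)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_calls
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=exocnv-%s", as.character(packageVersion("exocnv"))),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=NTARGETS,Number=1,Type=Integer,Description=\"Targets in segment\">",
    "##INFO=<ID=BF,Number=1,Type=Float,Description=\"log10 Bayes factor vs diploid\">",
    "##INFO=<ID=RATIO,Number=1,Type=Float,Description=\"Observed/expected depth ratio\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls) > 0L) {
    alt <- ifelse(calls$cnv_type == "deletion", "<DEL>", "<DUP>")
    svt <- ifelse(calls$cnv_type == "deletion", "DEL", "DUP")
    writeLines(sprintf(
      "%s\t%d\t%s\tN\t%s\t.\t.\tEND=%d;SVTYPE=%s;NTARGETS=%d;BF=%.4f;RATIO=%.4f",
      calls$chrom, calls$start + 1L,
      sprintf("%s_%s_%d", calls$sample_id, calls$chrom, calls$start + 1L),
      alt, calls$end, svt, calls$n_targets, calls$bf, calls$ratio), con)
  }
  invisible(path)
}
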