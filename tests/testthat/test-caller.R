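test_that("beta-binomial emission reduces to binomial as phi -> 0", {
  set.seed(3)
  for (k in 1:20) {
    n <- sample(50:500, 1)
    y <- rbinom(1, n, 0.3)
    p <- runif(1, 0.05, 0.95)
    state <- sample(c("CN1", "CN2", "CN3"), 1)
    q <- c(CN1 = 0.5, CN2 = 1, CN3 = 1.5)[[state]]
    p2 <- q * p / (q * p + 1 - p)
    expect_equal(emission_loglik(y, n, p, phi = 1e-9, state),
                 dbinom(y, n, p2, log = TRUE), tolerance = 1e-6)
    expect_equal(emission_loglik(y, n, p, phi = 0, state),
                 dbinom(y, n, p2, log = TRUE))
  }
})

test_that("copy-number odds scaling maps p as specified", {
  # CN2 leaves p untouched; CN1 at p = 0.5 gives p' = 1/3
  expect_equal(emission_loglik(10, 30, 0.5, 0, "CN1"),
               dbinom(10, 30, 1 / 3, log = TRUE))
  expect_equal(emission_loglik(10, 30, 0.4, 0, "CN2"),
               dbinom(10, 30, 0.4, log = TRUE))
  expect_error(emission_loglik(31, 30, 0.5, 0, "CN2"),
               class = "exocnv_state_error")
  expect_error(emission_loglik(10, 30, 1.2, 0, "CN2"),
               class = "exocnv_state_error")
})

test_that("overdispersion fit recovers the generating value", {
  set.seed(11)
  n_t <- 10000
  n <- rep(400L, n_t)
  p <- 0.08
  ref <- make_reference(aggregate = n - rbinom(n_t, n, p), p = p)
  # pure binomial: fitted phi collapses to (near) zero
  y <- rbinom(n_t, n, p)
  expect_lte(fit_overdispersion(y, ref), 1e-3)
  # beta-binomial with phi = 0.05: recovery within 20%
  phi <- 0.05
  pt <- rbeta(n_t, p / phi, (1 - p) / phi)
  y2 <- rbinom(n_t, n, pt)
  fit <- fit_overdispersion(y2, ref)
  expect_gt(fit, 0.8 * phi)
  expect_lt(fit, 1.2 * phi)
  expect_error(fit_overdispersion(y2[1], make_reference(400L, p)),
               class = "exocnv_state_error")
})

test_that("reference selection picks correlated controls", {
  set.seed(5)
  test <- rpois(200, rlnorm(200, log(200), 1))
  pool <- cbind(copy = test,
                noisy = rpois(200, 200),
                other = rpois(200, 200))
  ref <- select_reference(test, pool)
  expect_equal(ref$selected_controls[1], "copy")
  expect_true(length(ref$selected_controls) >= 1 &&
                all(ref$selected_controls %in% colnames(pool)))
  expect_error(select_reference(test, pool[, integer(0)]),
               class = "exocnv_state_error")
  expect_error(select_reference(rep(0, 200), pool),
               class = "exocnv_state_error")
})

test_that("greedy panel matches the exhaustive subset oracle on graded pools", {
  for (seed in 1:5) {
    fx <- make_graded_pool(seed)
    ref <- select_reference(fx$test, fx$pool)
    oracle <- oracle_best_subset(fx$test, fx$pool)
    expect_equal(sort(match(ref$selected_controls, colnames(fx$pool))),
                 oracle$set)
  }
})

test_that("reference model exposes tidy() and glance()", {
  fx <- make_graded_pool(1)
  ref <- select_reference(fx$test, fx$pool)
  td <- tidy(ref)
  expect_equal(td$control, ref$selected_controls)
  gl <- glance(ref)
  expect_equal(gl$n_controls, length(ref$selected_controls))
  expect_true(gl$r2 > 0 && gl$r2 <= 1)
})

test_that("proportional test counts give an all-diploid path and no calls", {
  tg <- toy_targets(20)
  agg <- rep(1000L, 20)
  ref <- make_reference(agg, p = 0.1)
  test <- round(agg * 0.1 / 0.9)  # exactly the expected test share
  res <- viterbi_segment(test, ref, tg, caller_params(phi = 0))
  expect_equal(nrow(res$calls), 0L)
  expect_true(all(res$path == "CN2"))
})

test_that("a spiked halved segment yields exactly one deletion call", {
  set.seed(21)
  n_t <- 100
  tg <- toy_targets(n_t)
  agg <- as.integer(rpois(n_t, 2000))
  p <- 0.1
  y <- as.integer(round(agg * p / (1 - p)))  # expected counts, depth >= 200
  y[40:44] <- as.integer(round(y[40:44] / 2))
  ref <- make_reference(agg, p = p)
  res <- viterbi_segment(y, ref, tg, caller_params(phi = 1e-4))
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$cnv_type, "deletion")
  expect_equal(res$calls$start, tg$start[40])
  expect_equal(res$calls$end, tg$end[44])
  expect_equal(res$calls$n_targets, 5L)
  expect_gt(res$calls$bf, 0)
  expect_equal(res$calls$ratio, 0.5, tolerance = 0.05)
})

test_that("Viterbi equals brute-force enumeration on short chromosomes", {
  for (seed in 1:20) {
    set.seed(seed)
    Tn <- sample(2:8, 1)
    tg <- toy_targets(Tn)
    agg <- as.integer(rpois(Tn, 500))
    p <- 0.1
    phi <- 0.01
    y <- as.integer(rbinom(Tn, agg, runif(Tn, 0.05, 0.25)))
    ref <- make_reference(agg, p = p, phi = phi)
    res <- viterbi_segment(y, ref, tg, caller_params(phi = phi))
    em <- sapply(c("CN1", "CN2", "CN3"), function(s) {
      emission_loglik(y, y + agg, rep(p, Tn), phi, s)
    })
    em <- matrix(em, nrow = Tn)
    oracle <- oracle_viterbi(em)
    got_path <- match(res$path, c("CN1", "CN2", "CN3"))
    expect_equal(got_path, unname(oracle$path))
  }
})

test_that("Bayes factor equals the per-term log-likelihood sum and accumulates", {
  set.seed(9)
  Tn <- 5
  agg <- as.integer(rpois(Tn, 2000))
  p <- 0.1
  phi <- 0.005
  y <- as.integer(round(agg * p / (1 - p) / 2))  # halved depth
  ref <- make_reference(agg, p = p, phi = phi)
  bf <- bayes_factor(1:Tn, "CN1", y, ref)
  hand <- 0
  for (i in 1:Tn) {
    hand <- hand + (emission_loglik(y[i], y[i] + agg[i], p, phi, "CN1") -
                      emission_loglik(y[i], y[i] + agg[i], p, phi, "CN2")) / log(10)
  }
  expect_equal(bf, hand, tolerance = 1e-12)
  expect_gt(bf, 0)
  # appending one more strongly supporting target increases bf
  bf4 <- bayes_factor(1:4, "CN1", y, ref)
  expect_gt(bf, bf4)
  expect_error(bayes_factor(integer(0), "CN1", y, ref),
               class = "exocnv_state_error")
})

test_that("call_sample finds the spiked deletion and nothing in flat samples", {
  fx <- spiked_cohort(seed = 42, events = tibble::tibble(
    sample = "S005", start_target = 40L, end_target = 42L, copy_number = 1L))
  calls <- call_sample("S005", fx$sim$counts, fx$targets)
  expect_equal(attr(calls, "status"), "ok")
  del <- dplyr::filter(calls, cnv_type == "deletion")
  expect_gte(nrow(del), 1L)
  expect_true(any(del$chrom == fx$sim$truth$chrom &
                    del$start < fx$sim$truth$end &
                    del$end > fx$sim$truth$start))
  flat <- call_sample("S010", fx$sim$counts, fx$targets)
  expect_equal(attr(flat, "status"), "ok")
  expect_lte(nrow(flat), 1L)
})

test_that("poorly correlated samples are rejected with a QC status", {
  fx <- spiked_cohort(seed = 7, events = NULL)
  counts <- fx$sim$counts
  set.seed(1)
  counts$S001 <- sample(counts$S001)  # destroy the target profile
  calls <- call_sample("S001", counts, fx$targets)
  expect_equal(attr(calls, "status"), "qc_failed")
  expect_lt(attr(calls, "r2"), 0.97)
  expect_equal(nrow(calls), 0L)
})

test_that("no-signal cohorts stay below 3 calls per 1000 targets", {
  cfg <- simulation_config(n_controls = 20, n_targets = 1000, chromosomes = 2,
                           mean_depth = 200, low_mappability_fraction = 0,
                           seed = 31)
  sim <- simulate_cohort(cfg)
  tg <- sim$targets
  tg$mean_mappability <- 1
  tg <- filter_by_mappability(tg)
  n_calls <- sapply(c("S001", "S002", "S003"), function(s) {
    nrow(call_sample(s, sim$counts, tg))
  })
  expect_lte(mean(n_calls), 3)
})

test_that("scaling all counts by 10 changes no call boundary on noiseless data", {
  n_t <- 60
  tg <- toy_targets(n_t)
  agg <- rep(1800L, n_t)
  y <- rep(200L, n_t)
  y[20:24] <- 100L
  ref1 <- make_reference(agg, p = sum(y) / (sum(y) + sum(agg)))
  c1 <- viterbi_segment(y, ref1, tg, caller_params(phi = 1e-4))$calls
  ref10 <- make_reference(agg * 10L, p = sum(y) / (sum(y) + sum(agg)))
  c10 <- viterbi_segment(y * 10L, ref10, tg, caller_params(phi = 1e-4))$calls
  expect_equal(c1[c("chrom", "start", "end", "cnv_type", "n_targets")],
               c10[c("chrom", "start", "end", "cnv_type", "n_targets")])
  expect_equal(nrow(c1), 1L)
})

test_that("calls export to TSV and VCF with symbolic alleles", {
  fx <- spiked_cohort(seed = 42)
  calls <- call_sample("S005", fx$sim$counts, fx$targets)
  tsv <- tempfile(fileext = ".tsv")
  write_calls(calls, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$start, calls$start + 1L)  # display is 1-based
  vcf <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, vcf)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(calls))
  expect_true(all(grepl("<DEL>|<DUP>", body)))
  expect_true(all(grepl("END=[0-9]+;SVTYPE", body)))
})
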