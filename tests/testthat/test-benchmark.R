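array_rec <- function(chrom = "chr1", start = 1001L, end = 1100L,
                      state = "het_del", n_probes = 10L, sample = "S001",
                      reported = FALSE) {
  tibble::tibble(sample_id = sample, chrom = chrom, start = start, end = end,
                 state = state, n_probes = n_probes,
                 clinically_reported = reported)
}

test_that("truth cascade drops chrY, low-probe and off-design records", {
  tg <- toy_targets(5)
  cnvs <- dplyr::bind_rows(
    array_rec(n_probes = 9L),                                  # probe stage
    array_rec(n_probes = 10L),                                 # kept
    array_rec(chrom = "chrY", n_probes = 50L),                 # chrY
    array_rec(start = 900000L, end = 900100L, n_probes = 20L)) # off-design
  ts <- truth_cascade(cnvs, tg, tg)
  expect_equal(ts$cascade_counts$n, c(4L, 2L, 1L))
  expect_equal(nrow(ts$truth), 1L)
  expect_equal(ts$truth$n_probes, 10L)
  # monotone non-increasing counts
  expect_true(all(diff(ts$cascade_counts$n) <= 0))
  expect_error(truth_cascade(array_rec(state = "weird"), tg, tg),
               "weird", class = "exocnv_parse_error")
})

test_that("a record overlapping an exon but no bait is dropped", {
  exons <- toy_targets(5)
  baits <- toy_targets(2)  # only first two targets baited
  cnv <- array_rec(start = exons$start[4] + 1L, end = exons$end[4])
  ts <- truth_cascade(cnv, exons, baits)
  expect_equal(nrow(ts$truth), 0L)
})

test_that("detection requires shared targets and compatible type", {
  tg <- toy_targets(10)
  call <- tibble::tibble(sample_id = "S001", chrom = "chr1",
                         start = tg$start[3], end = tg$end[5],
                         cnv_type = "deletion", n_targets = 3L,
                         bf = 10, ratio = 0.5)
  # truth exactly equal to the call
  expect_true(cnv_detected(array_rec(start = tg$start[3] + 1L,
                                     end = tg$end[5]), call, tg))
  # truth spanning 10 targets, call spanning 3 of them
  expect_true(cnv_detected(array_rec(start = tg$start[1] + 1L,
                                     end = tg$end[10]), call, tg))
  # opposite-type overlap does not count
  expect_false(cnv_detected(array_rec(start = tg$start[3] + 1L,
                                      end = tg$end[5], state = "dup"),
                            call, tg))
  # trip matches a duplication call
  dup_call <- dplyr::mutate(call, cnv_type = "duplication")
  expect_true(cnv_detected(array_rec(start = tg$start[3] + 1L,
                                     end = tg$end[5], state = "trip"),
                           dup_call, tg))
  # deletion zygosities all match a deletion call
  for (st in c("het_del", "hom_del", "hemi_del")) {
    expect_true(cnv_detected(array_rec(start = tg$start[3] + 1L,
                                       end = tg$end[5], state = st),
                             call, tg))
  }
})

test_that("sensitivity report reproduces printed-ratio arithmetic", {
  tg <- toy_targets(200)
  # 166 deletions of which 163 detected: deletion truth on targets 1..166,
  # calls covering all but targets 10, 20, 30
  truth <- dplyr::bind_rows(lapply(1:166, function(i) {
    array_rec(start = tg$start[i] + 1L, end = tg$end[i], sample = "S001")
  }))
  missed <- c(10L, 20L, 30L)
  calls <- dplyr::bind_rows(lapply(setdiff(1:166, missed), function(i) {
    tibble::tibble(sample_id = "S001", chrom = "chr1", start = tg$start[i],
                   end = tg$end[i], cnv_type = "deletion", n_targets = 1L,
                   bf = 10, ratio = 0.5)
  }))
  rep <- sensitivity_report(truth, calls, tg)
  overall_del <- dplyr::filter(rep, stratum == "overall", class == "deletions")
  expect_equal(overall_del$detected, 163L)
  expect_equal(overall_del$total, 166L)
  expect_equal(overall_del$pct, 98)
  # empty duplication stratum is undefined, not 0%
  overall_dup <- dplyr::filter(rep, stratum == "overall", class == "duplications")
  expect_true(is.na(overall_dup$pct))
  # zygosity denominators partition the overall deletion denominator
  zyg <- dplyr::filter(rep, stratum %in% c("het_del", "hom_del", "hemi_del"))
  expect_equal(sum(zyg$total), overall_del$total)
})

test_that("full detection yields 100% in every populated stratum", {
  tg <- toy_targets(50)
  truth <- dplyr::bind_rows(
    array_rec(start = tg$start[2] + 1L, end = tg$end[6], reported = TRUE),
    array_rec(start = tg$start[10] + 1L, end = tg$end[11], state = "dup"))
  calls <- tibble::tibble(
    sample_id = "S001", chrom = "chr1",
    start = tg$start[c(2, 10)], end = tg$end[c(6, 11)],
    cnv_type = c("deletion", "duplication"), n_targets = c(5L, 2L),
    bf = 10, ratio = c(0.5, 1.5))
  rep <- sensitivity_report(truth, calls, tg)
  populated <- dplyr::filter(rep, total > 0)
  expect_true(all(populated$pct == 100))
  # small/large split: the 2-exon dup is small, the 5-exon del is large
  expect_equal(dplyr::filter(rep, stratum == "small_cnv",
                             class == "duplications")$total, 1L)
  expect_equal(dplyr::filter(rep, stratum == "large_cnv",
                             class == "deletions")$total, 1L)
})

test_that("FDR protocol reproduces the review bookkeeping", {
  tg <- toy_targets(400, gap = 850L, width = 150L)
  probes <- tibble::tibble(chrom = "chr1",
                           pos = seq(1000L, max(tg$end) + 1000L, by = 10L))
  excl <- tibble::tibble(chrom = "chr9", start = 0L, end = 1L)
  mk_calls <- function(n, labels) {
    calls <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      tibble::tibble(sample_id = "S001", chrom = "chr1",
                     start = tg$start[i], end = tg$end[i],
                     cnv_type = "deletion", n_targets = 1L, bf = 5, ratio = 0.5)
    }))
    list(calls = calls,
         labels = dplyr::mutate(calls[c("sample_id", "chrom", "start", "end")],
                                label = labels))
  }
  # 149 reviewed, 17 false positives -> 11.4%
  fx <- mk_calls(149, c(rep("fp", 17), rep("tp_by_array", 132)))
  res <- fdr_protocol(fx$calls, probes, excl, fx$labels)
  expect_equal(res$n_reviewed, 149L)
  expect_equal(res$n_fp, 17L)
  expect_equal(res$fdr_pct, 11.4)
  # 225 reviewed, 103 array TPs + 23 review TPs -> 99 fp, 44%
  fx2 <- mk_calls(225, c(rep("tp_by_array", 103), rep("tp_by_review", 23),
                         rep("fp", 99)))
  res2 <- fdr_protocol(fx2$calls, probes, excl, fx2$labels)
  expect_equal(res2$n_fp, 99L)
  expect_equal(round(100 * res2$fdr), 44)
  # zero fp labels -> fdr 0
  fx3 <- mk_calls(10, rep("tp_by_array", 10))
  expect_equal(fdr_protocol(fx3$calls, probes, excl, fx3$labels)$fdr, 0)
})

test_that("FDR review excludes low-probe calls and exclusion regions", {
  tg <- toy_targets(5)
  probes <- tibble::tibble(chrom = "chr1", pos = c(tg$start[1] + 1:12))
  calls <- tibble::tibble(sample_id = "S001", chrom = "chr1",
                          start = tg$start[1:2], end = tg$end[1:2],
                          cnv_type = "deletion", n_targets = 1L,
                          bf = 5, ratio = 0.5)
  labels <- dplyr::mutate(calls[c("sample_id", "chrom", "start", "end")],
                          label = "fp")
  # call 1 covers 12 probes; call 2 covers none
  res <- fdr_protocol(calls, probes, tibble::tibble(chrom = character(),
                                                    start = integer(),
                                                    end = integer()), labels)
  expect_equal(res$n_reviewed, 1L)
  # an exclusion region over call 1 removes it from review
  res2 <- fdr_protocol(calls, probes,
                       tibble::tibble(chrom = "chr1", start = tg$start[1],
                                      end = tg$end[1]), labels)
  expect_equal(res2$n_reviewed, 0L)
  # order invariance
  res3 <- fdr_protocol(calls[2:1, ], probes[sample(nrow(probes)), ],
                       tibble::tibble(chrom = character(), start = integer(),
                                      end = integer()), labels)
  expect_equal(res3$n_reviewed, res$n_reviewed)
})

test_that("interval sizes follow the end-minus-start convention", {
  expect_equal(interval_size("chr12", "116,457,030", "116,460,406"), 3376L)
  expect_equal(interval_size("chr6", "33,405,980", "33,409,266"), 3286L)
  expect_equal(interval_size("chr4", "123,976,639", "123,989,201"), 12562L)
  expect_equal(interval_size("chr1", 100, 100), 0L)
  expect_error(interval_size("chr1", 200, 100), class = "exocnv_state_error")
})

test_that("packaged exclusion regions carry the KIR and HLA intervals", {
  bed <- default_exclusion_regions()
  expect_equal(nrow(bed), 2L)
  kir <- dplyr::filter(bed, chrom == "chr19")
  expect_equal(kir$start + 1L, 55236714L)  # display coordinates are 1-based
  expect_equal(kir$end, 55367367L)
  hla <- dplyr::filter(bed, chrom == "chr6")
  expect_equal(hla$start + 1L, 32549335L)
  expect_equal(hla$end, 32709302L)
})

test_that("array CNV TSV reader validates the state vocabulary", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(array_rec(), path)
  back <- read_array_cnvs(path)
  expect_equal(back$state, "het_del")
  readr::write_tsv(array_rec(state = "DEL"), path)
  expect_error(read_array_cnvs(path), class = "exocnv_parse_error")
})
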