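array_states <- c("het_del", "hom_del", "hemi_del", "dup", "trip")
del_states <- c("het_del", "hom_del", "hemi_del")

#' Read SNP-array CNV records
#'
#' TSV with columns `sample_id`, `chrom`, `start`, `end` (1-based
#' inclusive, as arrays export them), `state` (one of het_del, hom_del,
#' hemi_del, dup, trip), `n_probes`, and optional `clinically_reported`.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_array_cnvs <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  validate_array_cnvs(tb)
}

validate_array_cnvs <- function(tb) {
  tb <- as_tibble(tb)
  need <- c("sample_id", "chrom", "start", "end", "state", "n_probes")
  if (!all(need %in% names(tb))) {
    abort(paste0("array CNV table missing column(s): ",
                 paste(setdiff(need, names(tb)), collapse = ", ")),
          class = "exocnv_parse_error")
  }
  bad <- setdiff(unique(tb$state), array_states)
  if (length(bad) > 0L) {
    abort(paste0("unknown zygosity state token(s): ", paste(bad, collapse = ", ")),
          class = "exocnv_parse_error")
  }
  if (any(tb$start > tb$end)) {
    abort("array CNV with start > end", class = "exocnv_parse_error")
  }
  if (!"clinically_reported" %in% names(tb)) tb$clinically_reported <- FALSE
  tb
}

# 1-bp overlap between 1-based inclusive [s1,e1] and a 0-based half-open
# interval set given as (start0, end0) columns.
overlaps_any_bed <- function(chrom, start1, end1, bed) {
  map_lgl(seq_along(chrom), function(i) {
    any(bed$chrom == chrom[i] & bed$start + 1L <= end1[i] & bed$end >= start1[i])
  })
}

#' Filter array CNVs into a high-quality truth set
#'
#' Applies the staged truth-set cascade: drop chrY records (no usable
#' coverage on either platform), keep records with at least `min_probes`
#' supporting probes, then keep records overlapping at least one coding
#' exon and one capture bait by >= 1 bp. Stage counts are recorded so the
#' cascade can be reported.
#'
#' @param array_cnvs Array CNV tibble (see [read_array_cnvs()]).
#' @param exons,baits Target tibbles (0-based half-open intervals).
#' @param min_probes Minimum probe support (default 10; below it the
#'   array's own false-positive rate rises steeply).
#' @return A list of class `exocnv_truthset` with `truth` (surviving
#'   records) and `cascade_counts` (tibble stage/n).
#' @export
truth_cascade <- function(array_cnvs, exons, baits, min_probes = 10L) {
  array_cnvs <- validate_array_cnvs(array_cnvs)
  n_all <- nrow(array_cnvs)
  s1 <- filter(array_cnvs, !(.data$chrom %in% c("chrY", "Y")),
               .data$n_probes >= min_probes)
  keep <- overlaps_any_bed(s1$chrom, s1$start, s1$end, exons) &
    overlaps_any_bed(s1$chrom, s1$start, s1$end, baits)
  s2 <- s1[keep, ]
  structure(list(
    truth = s2,
    cascade_counts = tibble(
      stage = c("all", "min_probes", "exon_and_bait"),
      n = c(n_all, nrow(s1), nrow(s2))
    )
  ), class = "exocnv_truthset")
}

#' @export
print.exocnv_truthset <- function(x, ...) {
  cat("<exocnv_truthset>\n")
  for (i in seq_len(nrow(x$cascade_counts))) {
    cat(sprintf("  %-14s %d\n", x$cascade_counts$stage[i], x$cascade_counts$n[i]))
  }
  invisible(x)
}

compatible_type <- function(state, cnv_type) {
  (state %in% del_states & cnv_type == "deletion") |
    (state %in% c("dup", "trip") & cnv_type == "duplication")
}

#' Was a truth CNV detected by the exome calls?
#'
#' A truth record counts as detected when some call shares at least one
#' included target with it and is type-compatible (any deletion zygosity
#' matches a called deletion; duplications and triplications match a
#' called duplication).
#'
#' @param truth Array CNV tibble (1-based inclusive coordinates).
#' @param calls Call tibble from the caller.
#' @param targets Filtered target tibble.
#' @return Logical vector, one element per truth record.
#' @export
cnv_detected <- function(truth, calls, targets) {
  map_lgl(seq_len(nrow(truth)), function(i) {
    tt <- call_overlaps_targets(truth$chrom[i], truth$start[i] - 1L,
                                truth$end[i], targets)
    if (length(tt) == 0L || nrow(calls) == 0L) return(FALSE)
    ok <- compatible_type(truth$state[i], calls$cnv_type) &
      calls$chrom == truth$chrom[i]
    if (truth$sample_id[i] %in% calls$sample_id) {
      ok <- ok & calls$sample_id == truth$sample_id[i]
    }
    any(map_lgl(which(ok), function(j) {
      ct <- call_overlaps_targets(calls$chrom[j], calls$start[j],
                                  calls$end[j], targets)
      length(intersect(tt, ct)) > 0L
    }))
  })
}

truth_n_exons <- function(truth, targets) {
  map_int(seq_len(nrow(truth)), function(i) {
    length(call_overlaps_targets(truth$chrom[i], truth$start[i] - 1L,
                                 truth$end[i], targets))
  })
}

stratum_row <- function(stratum, class, det) {
  total <- length(det)
  detected <- sum(det)
  tibble(stratum = stratum, class = class, detected = detected, total = total,
         prop = if (total > 0) detected / total else NA_real_,
         pct = if (total > 0) round(100 * detected / total) else NA_real_)
}

#' Stratified sensitivity of exome calls against a truth set
#'
#' Computes detected/total per stratum: overall deletions and
#' duplications; deletion zygosity (het/hom/hemi) and duplication vs
#' triplication; autosomal vs chromosome X; clinically reported records;
#' and small (fewer than `small_cnv_exons` included exons) vs larger CNVs.
#' Display percentages are rounded to the nearest integer with the exact
#' proportion retained; empty strata report `NA`, never 0%.
#'
#' @param truth An `exocnv_truthset` or plain array CNV tibble.
#' @param calls Call tibble.
#' @param targets Filtered target tibble.
#' @param small_cnv_exons Small-CNV cutoff in included exons (default 4).
#' @return A tibble of class `exocnv_benchmark`: stratum, class,
#'   detected, total, prop, pct.
#' @export
sensitivity_report <- function(truth, calls, targets, small_cnv_exons = 4L) {
  if (inherits(truth, "exocnv_truthset")) truth <- truth$truth
  truth <- validate_array_cnvs(truth)
  det <- cnv_detected(truth, calls, targets)
  nex <- truth_n_exons(truth, targets)
  is_del <- truth$state %in% del_states
  is_x <- truth$chrom %in% c("chrX", "X")
  rows <- list(
    stratum_row("overall", "deletions", det[is_del]),
    stratum_row("overall", "duplications", det[!is_del]),
    stratum_row("het_del", "deletions", det[truth$state == "het_del"]),
    stratum_row("hom_del", "deletions", det[truth$state == "hom_del"]),
    stratum_row("hemi_del", "deletions", det[truth$state == "hemi_del"]),
    stratum_row("dup", "duplications", det[truth$state == "dup"]),
    stratum_row("trip", "duplications", det[truth$state == "trip"]),
    stratum_row("autosomal", "deletions", det[is_del & !is_x]),
    stratum_row("autosomal", "duplications", det[!is_del & !is_x]),
    stratum_row("chrX", "deletions", det[is_del & is_x]),
    stratum_row("chrX", "duplications", det[!is_del & is_x]),
    stratum_row("clinically_reported", "deletions",
                det[is_del & truth$clinically_reported]),
    stratum_row("clinically_reported", "duplications",
                det[!is_del & truth$clinically_reported]),
    stratum_row("small_cnv", "deletions", det[is_del & nex < small_cnv_exons]),
    stratum_row("small_cnv", "duplications", det[!is_del & nex < small_cnv_exons]),
    stratum_row("large_cnv", "deletions", det[is_del & nex >= small_cnv_exons]),
    stratum_row("large_cnv", "duplications", det[!is_del & nex >= small_cnv_exons])
  )
  out <- bind_rows(rows)
  class(out) <- c("exocnv_benchmark", class(out))
  out
}

#' @export
print.exocnv_benchmark <- function(x, ...) {
  cat("True-positive rate by stratum\n")
  wide <- tidyr::pivot_wider(
    as_tibble(x)[, c("stratum", "class", "detected", "total", "pct")],
    names_from = "class", values_from = c("detected", "total", "pct")
  )
  for (i in seq_len(nrow(wide))) {
    fmt <- function(p, d, t) {
      if (is.na(p)) "     --     " else sprintf("%3d%% (%d/%d)", p, d, t)
    }
    cat(sprintf("  %-20s del %s   dup %s\n", wide$stratum[i],
                fmt(wide$pct_deletions[i], wide$detected_deletions[i],
                    wide$total_deletions[i]),
                fmt(wide$pct_duplications[i], wide$detected_duplications[i],
                    wide$total_duplications[i])))
  }
  invisible(x)
}

#' False-discovery-rate review protocol
#'
#' Restricts calls to those assessable on the array — covering at least
#' `min_probes` probe positions (closed interval) and not overlapping any
#' polymorphic exclusion region — and computes the false discovery rate
#' from the supplied review labels. Labels encode the manual judgment
#' (`tp_by_array`: confirmed by the array pipeline; `tp_by_review`:
#' confirmed on manual inspection of probe-level signal; `fp`: false
#' positive); the function does only the bookkeeping.
#'
#' @param calls Call tibble.
#' @param probes Probe positions, tibble with `chrom`, `pos` (1-based).
#' @param exclusion_regions BED-style tibble (`chrom`, `start`, `end`,
#'   0-based half-open) of regions excluded from review; see
#'   [default_exclusion_regions()].
#' @param review_labels Tibble keyed by `sample_id`, `chrom`, `start`,
#'   `end` with a `label` column in {tp_by_array, tp_by_review, fp}.
#' @param min_probes Minimum probe support for a call to be reviewable
#'   (default 10).
#' @return A list with `reviewed` (labelled reviewable calls), `n_reviewed`,
#'   `n_fp`, `fdr` (fp / reviewed), `fdr_pct` (one decimal) and `tp_rate`.
#' @export
fdr_protocol <- function(calls, probes, exclusion_regions, review_labels,
                         min_probes = 10L) {
  n_probe <- map_int(seq_len(nrow(calls)), function(i) {
    sum(probes$chrom == calls$chrom[i] &
          probes$pos >= calls$start[i] + 1L & probes$pos <= calls$end[i])
  })
  excl <- map_lgl(seq_len(nrow(calls)), function(i) {
    any(exclusion_regions$chrom == calls$chrom[i] &
          exclusion_regions$start < calls$end[i] &
          exclusion_regions$end > calls$start[i])
  })
  reviewed <- calls[n_probe >= min_probes & !excl, , drop = FALSE]
  reviewed <- left_join(reviewed, review_labels,
                        by = c("sample_id", "chrom", "start", "end"))
  if (anyNA(reviewed$label)) {
    abort("reviewable call without a review label", class = "exocnv_state_error")
  }
  bad <- setdiff(unique(reviewed$label), c("tp_by_array", "tp_by_review", "fp"))
  if (length(bad) > 0L) {
    abort(paste0("unknown review label(s): ", paste(bad, collapse = ", ")),
          class = "exocnv_parse_error")
  }
  n_fp <- sum(reviewed$label == "fp")
  fdr <- if (nrow(reviewed) > 0) n_fp / nrow(reviewed) else NA_real_
  list(reviewed = reviewed, n_reviewed = nrow(reviewed), n_fp = n_fp,
       fdr = fdr, fdr_pct = round(100 * fdr, 1), tp_rate = 1 - fdr)
}

#' Genomic interval size under the end-minus-start convention
#'
#' Sizes of intervals printed 1-based inclusive are reported as
#' `end - start`. Comma-grouped coordinate strings are accepted.
#'
#' @param chrom Chromosome (unused in the arithmetic; kept so the call
#'   mirrors the printed coordinate triple).
#' @param start,end Coordinates, numeric or comma-formatted strings.
#' @return Integer size in bp.
#' @export
interval_size <- function(chrom, start, end) {
  num <- function(x) as.numeric(gsub(",", "", as.character(x)))
  s <- num(start); e <- num(end)
  if (any(e < s)) abort("end < start", class = "exocnv_state_error")
  as.integer(e - s)
}

#' Packaged polymorphic exclusion regions
#'
#' The two extremely polymorphic regions excluded from FDR review: the
#' killer-cell immunoglobulin-like receptor (KIR) cluster on chr19 and the
#' HLA region on chr6 (hg19 coordinates). Users may supply their own BED
#' instead.
#'
#' @return A BED-style tibble (`chrom`, `start`, `end`, `name`).
#' @export
default_exclusion_regions <- function() {
  read_bed3(system.file("extdata", "polymorphic_exclusion_hg19.bed",
                        package = "exocnv"))
}

#' Read a minimal BED3(+name) file
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and optional `name`.
#' @export
read_bed3 <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE)
  names(tb)[1:3] <- c("chrom", "start", "end")
  if (ncol(tb) >= 4L) names(tb)[4] <- "name"
  as_tibble(tb)
}

#' Read SNP-array probe positions
#'
#' Accepts BED3 (probe intervals; the start defines the position) or a
#' two-column (chrom, pos) file with 1-based positions.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `pos`.
#' @export
read_probes <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE)
  if (ncol(tb) >= 3L) {
    tibble(chrom = tb[[1]], pos = as.integer(tb[[2]]) + 1L)
  } else {
    tibble(chrom = tb[[1]], pos = as.integer(tb[[2]]))
  }
}
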