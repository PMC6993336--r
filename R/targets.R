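#' Read capture targets from a BED file
#'
#' Reads a BED3+ file of capture targets (exons or baits) into a target
#' tibble. Coordinates are kept in the BED convention (0-based, half-open)
#' internally; display helpers convert to 1-based inclusive. An optional
#' fourth column is interpreted as `GENE` or `GENE_exonN` and used both as
#' the gene symbol and the target id; targets without a name get the id
#' `chrom:start-end`.
#'
#' Duplicated intervals (identical chrom/start/end) are collapsed to a
#' single target with a warning, and the result is sorted by
#' (chrom, start).
#'
#' @param path Path to a BED file with at least 3 tab-separated columns.
#' @return A tibble with columns `chrom`, `start`, `end`, `gene`,
#'   `target_id`, `mean_mappability` (NA until annotated) and `included`
#'   (NA until filtered), sorted by (chrom, start).
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tGENE1_exon1", "chr1\t300\t400"), bed)
#' load_targets(bed)
load_targets <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("target BED file not found: ", path), class = "exocnv_io_error")
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(new_targets(tibble(
      chrom = character(), start = integer(), end = integer(),
      gene = character(), target_id = character()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) >= 3L
  if (any(!ncol_ok)) {
    abort(sprintf("line %d: expected >= 3 tab-separated columns", lineno[!ncol_ok][1]),
          class = "exocnv_parse_error")
  }
  chrom <- map_chr(fields, 1L)
  start_raw <- map_chr(fields, 2L)
  end_raw <- map_chr(fields, 3L)
  name <- map_chr(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_)
  start <- suppressWarnings(as.integer(start_raw))
  end <- suppressWarnings(as.integer(end_raw))
  bad_int <- is.na(start) | is.na(end) |
    start_raw != as.character(start) | end_raw != as.character(end)
  if (any(bad_int)) {
    abort(sprintf("line %d: non-integer coordinates '%s', '%s'",
                  lineno[bad_int][1], start_raw[bad_int][1], end_raw[bad_int][1]),
          class = "exocnv_parse_error")
  }
  bad_iv <- start >= end | start < 0L
  if (any(bad_iv)) {
    abort(sprintf("line %d: invalid interval %s:%d-%d (need 0 <= start < end)",
                  lineno[bad_iv][1], chrom[bad_iv][1], start[bad_iv][1], end[bad_iv][1]),
          class = "exocnv_parse_error")
  }
  tb <- tibble(
    chrom = chrom, start = start, end = end,
    gene = ifelse(is.na(name), "", sub("_exon[0-9]+$", "", name)),
    target_id = ifelse(is.na(name), sprintf("%s:%d-%d", chrom, start, end), name)
  )
  ndup <- sum(duplicated(tb[c("chrom", "start", "end")]))
  if (ndup > 0L) {
    warn(sprintf("collapsed %d duplicate target interval(s)", ndup))
    tb <- distinct(tb, .data$chrom, .data$start, .data$end, .keep_all = TRUE)
  }
  if (anyDuplicated(tb$target_id)) {
    tb$target_id <- make.unique(tb$target_id, sep = "_dup")
  }
  new_targets(arrange(tb, .data$chrom, .data$start))
}

new_targets <- function(tb) {
  if (!"mean_mappability" %in% names(tb)) tb$mean_mappability <- NA_real_
  if (!"included" %in% names(tb)) tb$included <- NA
  as_tibble(tb)
}

#' Build a mappability track from intervals
#'
#' Validates and normalises a base-level mappability track: per-chromosome
#' sorted, non-overlapping intervals each carrying a uniqueness score in
#' \[0, 1\] (0-based half-open coordinates).
#'
#' @param track A data frame with columns `chrom`, `start`, `end`, `score`.
#' @return A validated track tibble sorted by (chrom, start).
#' @export
mappability_track <- function(track) {
  track <- as_tibble(track)[, c("chrom", "start", "end", "score")]
  if (nrow(track) == 0L) return(track)
  if (any(track$start >= track$end)) {
    abort("track intervals must satisfy start < end", class = "exocnv_parse_error")
  }
  if (any(track$score < 0 | track$score > 1)) {
    abort("mappability scores must lie in [0, 1]", class = "exocnv_parse_error")
  }
  track <- arrange(track, .data$chrom, .data$start)
  ov <- track |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)])) |>
    pull(.data$bad)
  if (any(ov)) {
    abort("track intervals overlap within a chromosome", class = "exocnv_parse_error")
  }
  track
}

#' Read a mappability track from wig, bedGraph or bigWig
#'
#' Thin wrapper over [rtracklayer::import()]; the imported ranges are
#' converted to the package's 0-based half-open track tibble and validated.
#'
#' @param path Path to a `.wig`, `.bedGraph`/`.bg` or `.bw`/`.bigWig` file.
#' @return A track tibble as produced by [mappability_track()].
#' @export
read_mappability <- function(path) {
  gr <- rtracklayer::import(path)
  mappability_track(tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score)
  ))
}

targets_granges <- function(targets) {
  GenomicRanges::GRanges(
    seqnames = targets$chrom,
    ranges = IRanges::IRanges(start = targets$start + 1L, end = targets$end)
  )
}

#' Mean mappability of a single exon
#'
#' Base-wise arithmetic mean of the per-base mappability score over
#' `[start, end)`. Bases not covered by the track contribute score 0
#' (absent uniqueness data is treated as non-unique, the conservative
#' choice for filtering). A chromosome entirely absent from the track is
#' an error, distinct from partial coverage.
#'
#' @param chrom,start,end Exon coordinates, 0-based half-open.
#' @param track A mappability track tibble (see [mappability_track()]).
#' @return The mean score, a value in \[0, 1\].
#' @export
exon_mean_mappability <- function(chrom, start, end, track) {
  if (start >= end) abort("start must be < end", class = "exocnv_parse_error")
  if (!chrom %in% track$chrom) {
    abort(paste0("chromosome absent from mappability track: ", chrom),
          class = "exocnv_chrom_missing")
  }
  tr <- track[track$chrom == chrom, ]
  ov_start <- pmax(tr$start, start)
  ov_end <- pmin(tr$end, end)
  w <- pmax(0L, ov_end - ov_start)
  sum(w * tr$score) / (end - start)
}

#' Annotate targets with per-exon mean mappability
#'
#' Vectorised version of [exon_mean_mappability()]: fills the
#' `mean_mappability` column of a target tibble from a base-level track.
#'
#' @param targets A target tibble from [load_targets()].
#' @param track A mappability track tibble.
#' @return `targets` with `mean_mappability` set.
#' @export
annotate_mappability <- function(targets, track) {
  missing_chrom <- setdiff(unique(targets$chrom), unique(track$chrom))
  if (length(missing_chrom) > 0L) {
    abort(paste0("chromosome absent from mappability track: ",
                 paste(missing_chrom, collapse = ", ")),
          class = "exocnv_chrom_missing")
  }
  tgr <- targets_granges(targets)
  mgr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$score
  )
  hits <- GenomicRanges::findOverlaps(tgr, mgr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(targets$end[qi], track$end[si]) - pmax(targets$start[qi], track$start[si])
  contrib <- ov * track$score[si]
  total <- rep(0, nrow(targets))
  agg <- tapply(contrib, qi, sum)
  total[as.integer(names(agg))] <- as.numeric(agg)
  targets$mean_mappability <- total / (targets$end - targets$start)
  targets
}

#' Partition targets by mean mappability
#'
#' Applies the low-mappability exclusion rule: a target with mean
#' mappability less than or equal to `threshold` is excluded (the boundary
#' value itself is excluded). Order is preserved and the partition is
#' recorded in the `included` column.
#'
#' @param targets A target tibble with `mean_mappability` set for every row.
#' @param threshold Exclusion threshold; targets with mean mappability
#'   `<= threshold` are excluded. Default 0.75, which retains only regions
#'   effectively unique for 35-mer reads.
#' @return `targets` with the logical `included` column filled in.
#' @export
filter_by_mappability <- function(targets, threshold = 0.75) {
  if (anyNA(targets$mean_mappability)) {
    abort("mean_mappability unset for one or more targets; run annotate_mappability() first",
          class = "exocnv_state_error")
  }
  targets$included <- targets$mean_mappability > threshold
  targets
}

#' Included / excluded subsets of a filtered target set
#' @param targets A target tibble with the `included` column filled.
#' @return The included (resp. excluded) rows, order preserved.
#' @export
included_targets <- function(targets) {
  if (anyNA(targets$included)) {
    abort("targets not yet filtered; run filter_by_mappability()",
          class = "exocnv_state_error")
  }
  targets[targets$included, ]
}

#' @rdname included_targets
#' @export
excluded_targets <- function(targets) {
  if (anyNA(targets$included)) {
    abort("targets not yet filtered; run filter_by_mappability()",
          class = "exocnv_state_error")
  }
  targets[!targets$included, ]
}

#' Write a target set as BED
#'
#' Column 4 is the target id, column 5 the mean mappability scaled to
#' \[0, 1000\] (BED score convention), column 6 the strand placeholder and
#' column 7 the exact mean mappability.
#'
#' @param targets A target tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_bed <- function(targets, path) {
  score <- ifelse(is.na(targets$mean_mappability), 0,
                  round(targets$mean_mappability * 1000))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s",
                   targets$chrom, targets$start, targets$end,
                   targets$target_id, as.integer(score),
                   ifelse(is.na(targets$mean_mappability), "NA",
                          format(targets$mean_mappability, digits = 10)))
  writeLines(lines, path)
  invisible(path)
}
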