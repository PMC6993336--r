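#' @noRd
str_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' Checksum of a target set
#'
#' A stable digest of the ordered target ids, embedded in count-matrix
#' files so the caller can refuse a matrix produced against a different
#' target set.
#'
#' @param targets A target tibble.
#' @return A character md5 digest.
#' @export
target_checksum <- function(targets) {
  str_md5(paste(targets$target_id, collapse = "\n"))
}

validate_count_matrix <- function(counts) {
  counts <- as_tibble(counts)
  if (!"target_id" %in% names(counts)) {
    abort("count matrix must have a target_id column", class = "exocnv_parse_error")
  }
  for (s in setdiff(names(counts), "target_id")) {
    v <- counts[[s]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0L) {
      abort(sprintf("invalid count at target '%s', sample '%s': %s",
                    counts$target_id[bad[1]], s, as.character(v[bad[1]])),
            class = "exocnv_parse_error")
    }
    counts[[s]] <- as.integer(round(v))
  }
  counts
}

#' Sample ids of a count matrix
#' @param counts A count-matrix tibble (`target_id` plus one column per sample).
#' @return Character vector of sample ids.
#' @export
count_samples <- function(counts) setdiff(names(counts), "target_id")

#' Count fragments per target from an alignment file
#'
#' Counts sequencing fragments overlapping each capture target. A fragment
#' is counted once per target it overlaps by at least 1 bp of aligned span,
#' provided its alignment is primary, mapped, not duplicate-flagged, not
#' secondary/supplementary and has mapping quality `>= min_mapq`. Read
#' pairs are collapsed by query name so a pair contributes one fragment
#' per target.
#'
#' @param path A coordinate-sorted, indexed BAM file, or a SAM file
#'   (converted on the fly).
#' @param targets A target tibble; counting is restricted to these rows.
#' @param min_mapq Minimum mapping quality (default 20, excluding
#'   multi-mapping reads).
#' @param sample_id Column name for the resulting counts (default: file
#'   basename without extension).
#' @return A one-sample count-matrix tibble (`target_id`, `<sample_id>`).
#' @export
count_alignments <- function(path, targets, min_mapq = 20L, sample_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path), class = "exocnv_io_error")
  }
  sample_id <- sample_id %||% sub("\\.(bam|sam)$", "", basename(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam))) {
      abort(paste0("BAM file is not indexed: ", bam,
                   " (sort and index it before counting)"),
            class = "exocnv_io_error")
    }
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_chrom <- setdiff(unique(targets$chrom), names(hdr))
  if (length(missing_chrom) > 0L) {
    abort(paste0("target chromosomes absent from alignment header: ",
                 paste(missing_chrom, collapse = ", ")),
          class = "exocnv_chrom_missing")
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isDuplicate = FALSE, isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq,
                                   what = "qname")
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  tgr <- targets_granges(targets)
  hits <- GenomicRanges::findOverlaps(tgr, GenomicRanges::granges(aln))
  qname <- S4Vectors::mcols(aln)$qname[S4Vectors::subjectHits(hits)]
  ti <- S4Vectors::queryHits(hits)
  n <- integer(nrow(targets))
  if (length(ti) > 0L) {
    uniq <- !duplicated(paste0(ti, "\r", qname))
    cnt <- table(ti[uniq])
    n[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out <- tibble(target_id = targets$target_id)
  out[[sample_id]] <- n
  out
}

#' Read / write a per-target count matrix
#'
#' The on-disk format is TSV with a `target_id` first column and one
#' integer column per sample, preceded by a `#`-prefixed comment header
#' carrying the target-set checksum; [read_counts()] returns the checksum
#' as the `"target_checksum"` attribute so downstream steps can refuse a
#' matrix built against a different target set. Round trip is the
#' identity.
#'
#' @param path File path.
#' @return For `read_counts`, a validated count-matrix tibble.
#' @export
read_counts <- function(path) {
  lines <- readLines(path, n = 50L)
  checksum <- NA_character_
  m <- regmatches(lines, regexec("^#.*target_checksum=([0-9a-f]+)", lines))
  for (g in m) if (length(g) == 2L) checksum <- g[2]
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          target_id = readr::col_character(),
                          .default = readr::col_double()
                        ))
  tb <- validate_count_matrix(tb)
  attr(tb, "target_checksum") <- checksum
  tb
}

#' @param counts A count-matrix tibble.
#' @param targets Optional target tibble used to embed the target-set
#'   checksum in the file header.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path, targets = NULL) {
  counts <- validate_count_matrix(counts)
  checksum <- if (!is.null(targets)) target_checksum(targets)
    else attr(counts, "target_checksum") %||% str_md5(paste(counts$target_id, collapse = "\n"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# exocnv counts v1 target_checksum=%s", checksum), con)
  writeLines(paste(names(counts), collapse = "\t"), con)
  body <- do.call(paste, c(unname(as.list(counts)), sep = "\t"))
  if (length(body) > 0L) writeLines(body, con)
  invisible(path)
}

#' Does a squared correlation pass the QC gate?
#'
#' The gate is inclusive at the threshold: exactly 0.97 passes, anything
#' strictly below fails.
#'
#' @param r2 Squared Pearson correlation between test and aggregate
#'   reference.
#' @param threshold Minimum acceptable value (default 0.97).
#' @return Logical.
#' @export
passes_qc <- function(r2, threshold = 0.97) {
  !is.na(r2) & r2 >= threshold
}

#' Correlation QC between a test sample and its reference aggregate
#'
#' Squared Pearson correlation of per-target counts between a test sample
#' and the aggregated reference panel, computed over the
#' mappability-included target set. The caller refuses samples below
#' r-squared 0.97, the quality gate recommended for reliable read-depth
#' CNV calling.
#'
#' @param test,reference Equal-length numeric vectors of per-target counts.
#' @return The squared Pearson correlation, in \[0, 1\].
#' @export
correlation_qc <- function(test, reference) {
  if (length(test) != length(reference)) {
    abort("test and reference must have equal length", class = "exocnv_state_error")
  }
  if (length(test) < 3L) {
    abort("need at least 3 targets for correlation QC", class = "exocnv_state_error")
  }
  if (stats::sd(test) == 0 || stats::sd(reference) == 0) {
    abort("zero-variance count vector in correlation QC", class = "exocnv_state_error")
  }
  cor(test, reference)^2
}
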