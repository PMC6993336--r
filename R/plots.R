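#' Plot per-target depth ratio with calls overlaid
#'
#' Observed/expected test depth per included target along one chromosome,
#' with called segments shaded (deletions below, duplications above the
#' diploid line).
#'
#' @param test Test counts over the included targets.
#' @param reference An `exocnv_reference`.
#' @param targets Included target tibble aligned with `test`.
#' @param calls Call tibble for the sample (may be empty).
#' @param chrom Chromosome to draw (default: first in `targets`).
#' @return A ggplot object.
#' @export
plot_depth_ratio <- function(test, reference, targets, calls = NULL,
                             chrom = targets$chrom[1]) {
  idx <- which(targets$chrom == chrom & !is.na(reference$p))
  p <- reference$p[idx]
  expected <- p / (1 - p) * reference$aggregate[idx]
  df <- tibble(pos = (targets$start[idx] + targets$end[idx]) / 2,
               ratio = test[idx] / pmax(expected, 1e-9))
  g <- ggplot(df, aes(x = .data$pos, y = .data$ratio)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = paste0(chrom, " position (bp)"), y = "observed / expected depth") +
    theme_bw()
  if (!is.null(calls) && nrow(calls) > 0L) {
    cc <- filter(calls, .data$chrom == !!chrom)
    if (nrow(cc) > 0L) {
      g <- g + geom_rect(
        data = mutate(cc, ymin = ifelse(.data$cnv_type == "deletion", 0, 1),
                      ymax = ifelse(.data$cnv_type == "deletion", 1, Inf)),
        aes(xmin = .data$start, xmax = .data$end, ymin = .data$ymin,
            ymax = .data$ymax, fill = .data$cnv_type),
        alpha = 0.25, inherit.aes = FALSE
      )
    }
  }
  g
}

#' Plot a stratified sensitivity report
#' @param object An `exocnv_benchmark` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exocnv_benchmark <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$pct))
  ggplot(df, aes(x = .data$stratum, y = .data$pct, fill = .data$class)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "true-positive rate (%)", fill = NULL) +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot reproducibility scores
#'
#' Detection count per call over the resampling iterations, ordered from
#' most to least reproducible, with an optional confidence threshold line.
#'
#' @param scores Scored call tibble from [score_reproducibility()].
#' @param threshold Optional detection-count threshold to draw.
#' @return A ggplot object.
#' @export
plot_reproducibility <- function(scores, threshold = NULL) {
  df <- arrange(scores, dplyr::desc(.data$n_detected))
  df$rank <- seq_len(nrow(df))
  g <- ggplot(df, aes(x = .data$rank, y = .data$n_detected,
                      colour = .data$cnv_type)) +
    geom_point(size = 1) +
    labs(x = "call rank", y = "iterations detected", colour = NULL) +
    theme_bw()
  if (!is.null(threshold)) g <- g + geom_hline(yintercept = threshold,
                                               linetype = "dashed")
  g
}
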