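#' Tumor mutational burden
#'
#' Non-synonymous mutation count divided by the size of the sequenced capture
#' panel in megabases.
#'
#' @param n_nonsynonymous Mutation count(s), non-negative.
#' @param panel_size_mb Capture panel size in megabases (positive).
#' @return Mutations per megabase (vectorised over `n_nonsynonymous`).
#' @examples
#' tmb(30, 1.5) # 20 mutations/Mb
#' @export
tmb <- function(n_nonsynonymous, panel_size_mb) {
  if (length(panel_size_mb) != 1L || !is.finite(panel_size_mb) || panel_size_mb <= 0)
    abort("panel_size_mb must be a single positive number")
  if (any(n_nonsynonymous < 0)) abort("negative mutation count")
  n_nonsynonymous / panel_size_mb
}

#' Fraction of genome altered
#'
#' Cumulative length of segments whose copy-number ratio exceeds a threshold,
#' divided by the cumulative length of all measured segments. By default the
#' threshold applies to the absolute value (gains and losses both count,
#' matching the common portal convention); `signed = TRUE` counts only
#' `value > threshold`.
#'
#' @param segments Tibble with columns `start`, `end`, `value` (log2 or
#'   linear copy-number ratios) and optionally `sample`.
#' @param threshold Alteration threshold, default 0.2.
#' @param signed If `TRUE`, only positive deviations count.
#' @return A single fraction in \[0, 1\], or a tibble (`sample`, `fga`) when
#'   a `sample` column is present.
#' @export
fga <- function(segments, threshold = 0.2, signed = FALSE) {
  stopifnot(all(c("start", "end", "value") %in% names(segments)))
  if (nrow(segments) == 0L) abort("empty segment list")
  one <- function(seg) {
    len <- seg$end - seg$start + 1
    altered <- if (signed) seg$value > threshold else abs(seg$value) > threshold
    sum(len[altered]) / sum(len)
  }
  if ("sample" %in% names(segments)) {
    out <- summarise(group_by(segments, .data$sample),
                     fga = one(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
    return(out)
  }
  one(segments)
}

#' Large-scale state transition score
#'
#' Counts chromosomal breakpoints flanked on both sides by segments in
#' different allele-aware copy states each spanning at least
#' `min_segment_mb` megabases. A score of at least `high_cutoff` flags the
#' sample as LST-high (a proxy for homologous recombination deficiency).
#' Optional pre-smoothing (off by default) drops segments shorter than
#' `smooth_mb` and merges adjacent segments left in identical states.
#'
#' @param segments Tibble with columns `chrom`, `start`, `end`, `state`
#'   (allele-aware copy state, any comparable value) and optionally
#'   `sample`. Coordinates in base pairs, 1-based inclusive.
#' @param min_segment_mb Minimum flanking segment span in Mb (default 10).
#' @param high_cutoff Score labelling a sample LST-high (default 15).
#' @param smooth If `TRUE`, apply the short-segment pre-smoothing.
#' @param smooth_mb Segments shorter than this are dropped when smoothing
#'   (default 3 Mb).
#' @return Tibble with columns `sample` (if provided), `lst`, `lst_high`.
#' @export
lst_score <- function(segments, min_segment_mb = 10, high_cutoff = 15,
                      smooth = FALSE, smooth_mb = 3) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(segments)))
  has_sample <- "sample" %in% names(segments)
  if (!has_sample) segments$sample <- "."
  mb <- 1e6

  count_chrom <- function(seg) {
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)]))
      abort("overlapping segments on one chromosome")
    if (smooth) {
      seg <- seg[(seg$end - seg$start + 1) >= smooth_mb * mb, , drop = FALSE]
      if (nrow(seg) > 1L) {
        run <- cumsum(c(TRUE, seg$state[-1L] != seg$state[-nrow(seg)]))
        seg <- summarise(group_by(seg, run = run),
                         chrom = .data$chrom[1L], start = min(.data$start),
                         end = max(.data$end), state = .data$state[1L],
                         .groups = "drop")
      }
    }
    if (nrow(seg) < 2L) return(0L)
    len <- seg$end - seg$start + 1
    big <- len >= min_segment_mb * mb
    i <- seq_len(nrow(seg) - 1L)
    sum(big[i] & big[i + 1L] & seg$state[i] != seg$state[i + 1L])
  }

  res <- lapply(split(segments, segments$sample), function(ss) {
    tibble(sample = ss$sample[1L],
           lst = sum(vapply(split(ss, ss$chrom), count_chrom, 0L)))
  })
  out <- mutate(bind_rows(res), lst_high = .data$lst >= high_cutoff)
  if (!has_sample) out$sample <- NULL
  out
}

#' Combine genomic features into one table
#'
#' Convenience wrapper joining [tmb()], [fga()] and [lst_score()] results
#' into a per-sample feature table ready to merge with a clinical table.
#'
#' @param mutations Tibble with columns `sample`, `n_nonsyn`.
#' @param panel_size_mb Capture panel size in megabases.
#' @param ratio_segments Segments with real-valued ratios for [fga()].
#' @param state_segments Segments with allele-aware states for [lst_score()];
#'   optional.
#' @return Tibble with columns `sample`, `tmb`, `fga` and (when state
#'   segments are given) `lst`, `lst_high`.
#' @export
genomic_features <- function(mutations, panel_size_mb, ratio_segments,
                             state_segments = NULL) {
  stopifnot(all(c("sample", "n_nonsyn") %in% names(mutations)))
  out <- tibble(sample = as.character(mutations$sample),
                tmb = tmb(mutations$n_nonsyn, panel_size_mb))
  out <- left_join(out, fga(ratio_segments), by = "sample")
  if (!is.null(state_segments))
    out <- left_join(out, lst_score(state_segments), by = "sample")
  out
}
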