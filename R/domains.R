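#' Genome-wide average of a linear signal track
#'
#' Arithmetic mean over all chromosomal probes; spike-in control probes are
#' excluded. This is the reference level against which enriched domains are
#' thresholded.
#'
#' @param track a linear-scale `probe_track`.
#' @return the mean linear signal.
#' @export
genome_wide_average <- function(track) {
  stopifnot(inherits(track, "probe_track"))
  if (track_scale(track) != "linear")
    stop("genome-wide average is defined on the linear scale")
  keep <- .chromosomal(track)
  if (!any(keep)) stop("track has no chromosomal probes")
  mean(track$value[keep])
}

#' Call enriched domains from a linear ratio track
#'
#' Implements the published domain rule: probes whose value exceeds
#' `fold_threshold` times the genome-wide average (strictly greater,
#' "more than 2-fold") are marked, maximal runs of marked probes — allowing
#' up to `max_gap` consecutive unmarked probes inside a run — become
#' candidate regions, and candidates shorter than `min_length` are
#' discarded. A region's span is `[first probe position, last probe position
#' + spacing)`, so an n-probe run has length n x spacing on an even grid.
#'
#' @param track linear-scale `probe_track` (typically the spike-normalized
#'   mutant/wild-type ratio). Probes must be evenly spaced within each
#'   chromosome at the track's declared spacing.
#' @param min_length minimum region span in bp (default 1000).
#' @param fold_threshold fold over the genome-wide average a probe must
#'   exceed (default 2).
#' @param max_gap number of consecutive sub-threshold probes tolerated
#'   inside a region (default 0, the conservative reading).
#' @return a data.frame of class `enriched_regions`: `chrom`, `start`,
#'   `end` (0-based half-open), `n_probes` (all probes in the span) and
#'   `mean_fold` (mean linear ratio over those probes), sorted by
#'   coordinate. Zero rows when nothing qualifies.
#' @export
call_enriched_regions <- function(track, min_length = 1000,
                                  fold_threshold = 2, max_gap = 0) {
  stopifnot(inherits(track, "probe_track"),
            min_length > 0, fold_threshold > 0, max_gap >= 0)
  if (track_scale(track) != "linear")
    stop("domain calling operates on the linear scale")
  sp <- track_spacing(track)
  cutoff <- fold_threshold * genome_wide_average(track)

  keep <- .chromosomal(track)
  out <- list()
  for (ch in unique(track$chrom[keep])) {
    sel <- which(track$chrom == ch)
    pos <- track$pos[sel]
    if (length(pos) > 1 && length(unique(diff(pos))) != 1L)
      stop("mixed probe spacing on ", ch)
    v <- track$value[sel]
    marked <- v > cutoff
    runs <- .gapped_runs(marked, max_gap)
    for (r in runs) {
      start <- pos[r[1]]
      end <- pos[r[2]] + sp
      if (end - start < min_length) next
      idx <- sel[r[1]:r[2]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = start, end = end,
        n_probes = r[2] - r[1] + 1L,
        mean_fold = mean(track$value[idx]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_probes = integer(), mean_fold = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enriched_regions", "data.frame")
  res
}

# maximal runs of TRUE allowing <= max_gap consecutive FALSE inside; returns
# list of c(first_index, last_index), endpoints always TRUE probes
.gapped_runs <- function(marked, max_gap) {
  idx <- which(marked)
  if (length(idx) == 0) return(list())
  breaks <- which(diff(idx) > max_gap + 1)
  starts <- idx[c(1, breaks + 1)]
  ends <- idx[c(breaks, length(idx))]
  Map(c, starts, ends)
}
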