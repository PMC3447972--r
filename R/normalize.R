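#' Spike-in scale factor for one array
#'
#' The single scalar that makes the mean of the track's spike-in control
#' probes equal the mean of the known spike references. Because the spike-in
#' material has condition-invariant abundance, this factor absorbs array-level
#' differences in amplification and hybridization efficiency and puts arrays
#' on a common absolute scale.
#'
#' @param track a linear-scale `probe_track` containing the spike contig.
#' @param spikes a `spike_in_set`.
#' @return the positive scalar factor.
#' @export
spike_scale_factor <- function(track, spikes) {
  stopifnot(inherits(track, "probe_track"), inherits(spikes, "spike_in_set"))
  if (track_scale(track) != "linear")
    stop("spike scaling operates on linear-scale tracks")
  if (nrow(spikes) == 0) stop("empty spike-in set")
  key <- paste(spikes$chrom, spikes$pos)
  idx <- match(key, paste(track$chrom, track$pos))
  if (anyNA(idx)) stop("track is missing spike-in probes")
  obs_mean <- mean(track$value[idx])
  if (!is.finite(obs_mean) || obs_mean <= 0)
    stop("non-positive spike-in mean; cannot scale")
  mean(spikes$reference) / obs_mean
}

#' Scale a track by its spike-in controls
#'
#' Multiplies every probe (chromosomal and control) by the
#' [spike_scale_factor()], so the track's spike-in mean equals the reference
#' mean. Rank order of chromosomal probes is unchanged, and the operation is
#' idempotent.
#'
#' @inheritParams spike_scale_factor
#' @return the rescaled `probe_track`.
#' @export
scale_by_spike_ins <- function(track, spikes) {
  f <- spike_scale_factor(track, spikes)
  .with_values(track, track$value * f)
}

#' Per-probe condition ratio track
#'
#' @param mut,wt `probe_track`s on the same probe grid and scale.
#' @param scale scale of the returned ratio: `"linear"` (mut/wt) or
#'   `"log2"`.
#' @return a `probe_track` of per-probe ratios on the requested scale.
#' @export
ratio_track <- function(mut, wt, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(inherits(mut, "probe_track"), inherits(wt, "probe_track"))
  .check_same_grid(mut, wt)
  ml <- as_linear(mut); wl <- as_linear(wt)
  if (any(wl$value == 0)) stop("division by zero in ratio track")
  r <- ml$value / wl$value
  if (scale == "log2") r <- log2(r)
  .with_values(mut, r, scale = scale)
}

#' Centered running average over probes
#'
#' Smooths each chromosome independently with a centered moving mean over
#' `window` probes (the display convention "running average signal/100
#' probes"). Even windows are incremented to the next odd integer so the
#' window is symmetric; at chromosome ends the window shrinks (truncated
#' mean) rather than padding with invented data. The probe grid is
#' preserved.
#'
#' @param track a `probe_track` (either scale).
#' @param window window size in probes (default 100).
#' @return the smoothed `probe_track`.
#' @export
running_average <- function(track, window = 100) {
  stopifnot(inherits(track, "probe_track"), window >= 1)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  out <- track$value
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    v <- track$value[sel]
    m <- length(v)
    if (window > m)
      stop("window (", window, " probes) exceeds probe count on ", ch)
    cs <- cumsum(c(0, v))
    i <- seq_len(m)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, m)
    out[sel] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  .with_values(track, out)
}

#' Spike-in-normalized global fold change between conditions
#'
#' Scales both arrays to the common spike-in reference, then summarizes the
#' genome-wide mutant/wild-type ratio as the geometric mean of per-probe
#' ratios over chromosomal (non-control) probes: `2^mean(log2(mut/wt))`.
#' The geometric mean is unbiased under the symmetric log-scale noise model,
#' and spike normalization makes the estimate invariant to multiplying
#' either input array by any positive constant.
#'
#' @param mut,wt linear-scale `probe_track`s on the same grid, spike contig
#'   included.
#' @param spikes the `spike_in_set` shared by both arrays.
#' @return the global fold change (linear scale).
#' @export
estimate_global_fold_change <- function(mut, wt, spikes) {
  mutn <- scale_by_spike_ins(mut, spikes)
  wtn <- scale_by_spike_ins(wt, spikes)
  .check_same_grid(mutn, wtn)
  keep <- .chromosomal(mutn)
  lr <- log2(mutn$value[keep]) - log2(wtn$value[keep])
  2^mean(lr)
}
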