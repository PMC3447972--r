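#' Probe-level signal tracks
#'
#' A `probe_track` is the central signal carrier: an ordered table of
#' (chrom, pos, value) triples on a regular probe grid, plus a declared
#' scale (`"linear"` or `"log2"`) and the probe spacing in bp. Exogenous
#' spike-in control probes live on their own virtual contig (named in the
#' `control_chroms` attribute) so chromosomal coordinates stay clean;
#' chromosomal summaries exclude them.
#'
#' @param probes data.frame with columns `chrom`, `pos` (bp, 0-based probe
#'   start) and `value`; positions must be strictly increasing within each
#'   chromosome.
#' @param scale `"linear"` (values > 0) or `"log2"` (unbounded).
#' @param spacing probe spacing in bp.
#' @param control_chroms character vector of contig names holding spike-in
#'   control probes rather than chromosomal probes.
#' @return a `probe_track` object.
#' @export
probe_track <- function(probes, scale = c("linear", "log2"), spacing,
                        control_chroms = character()) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(probes),
            all(c("chrom", "pos", "value") %in% names(probes)),
            is.numeric(spacing), length(spacing) == 1L, spacing > 0)
  probes <- probes[, c("chrom", "pos", "value")]
  split_pos <- split(probes$pos, probes$chrom)
  if (!all(vapply(split_pos, function(p) all(diff(p) > 0), logical(1))))
    stop("probe positions must be strictly increasing within each chromosome")
  if (scale == "linear" && any(probes$value <= 0))
    stop("linear-scale probe values must be positive")
  structure(probes,
            scale = scale, spacing = spacing,
            control_chroms = control_chroms,
            class = c("probe_track", "data.frame"))
}

#' @rdname probe_track
#' @param x a `probe_track`.
#' @export
track_scale <- function(x) attr(x, "scale")

#' @rdname probe_track
#' @export
track_spacing <- function(x) attr(x, "spacing")

#' @rdname probe_track
#' @export
control_chroms <- function(x) attr(x, "control_chroms")

# logical index of chromosomal (non-control) probes
.chromosomal <- function(x) !(x$chrom %in% control_chroms(x))

# rebuild a track with new values, keeping grid and attributes
.with_values <- function(x, values, scale = track_scale(x)) {
  probe_track(data.frame(chrom = x$chrom, pos = x$pos, value = values,
                         stringsAsFactors = FALSE),
              scale = scale, spacing = track_spacing(x),
              control_chroms = control_chroms(x))
}

#' Convert a track between linear and log2 scales
#'
#' The conversions are exact inverses: `as_linear(as_log2(x))` reproduces
#' `x` up to floating-point tolerance.
#'
#' @param x a `probe_track`.
#' @return the track on the requested scale (unchanged if already there).
#' @export
as_log2 <- function(x) {
  stopifnot(inherits(x, "probe_track"))
  if (track_scale(x) == "log2") return(x)
  .with_values(x, log2(x$value), scale = "log2")
}

#' @rdname as_log2
#' @export
as_linear <- function(x) {
  stopifnot(inherits(x, "probe_track"))
  if (track_scale(x) == "linear") return(x)
  .with_values(x, 2^x$value, scale = "linear")
}

#' @export
print.probe_track <- function(x, ...) {
  n_ctrl <- sum(!.chromosomal(x))
  cat("probe_track:", nrow(x) - n_ctrl, "chromosomal probes",
      if (n_ctrl > 0) paste0("+ ", n_ctrl, " control probes"),
      "| scale", track_scale(x), "| spacing", track_spacing(x), "bp\n")
  invisible(x)
}

# assert two tracks share an identical probe grid
.check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) || !identical(a$pos, b$pos))
    stop("probe grids differ between tracks")
  if (track_spacing(a) != track_spacing(b))
    stop("probe spacing differs between tracks")
  invisible(TRUE)
}
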