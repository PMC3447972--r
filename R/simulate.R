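#' Simulation parameters for synthetic ChIP-chip tracks
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: a flat wild-type baseline, a mutant condition carrying (i) a
#' uniform global multiplier on all chromosomal signal, (ii) planted
#' enrichment domains of fixed linear fold, and (iii) transcription-coupled
#' histone depletion over gene bodies whose log2 depth is proportional to
#' the gene's expression value. Measurement noise is Gaussian on the log2
#' scale (multiplicative on linear), the standard tiling-array error model.
#' Spike-in control probes of known, condition-invariant abundance are
#' appended on a separate virtual contig.
#'
#' @param probe_spacing probe spacing in bp (default 20, oligo tiling
#'   resolution).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale
#'   applied to chromosomal probes of both conditions (default 0.25).
#' @param domains data.frame of planted domains with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `fold` (linear enrichment in the
#'   mutant); `NULL` or zero rows plants nothing. Overlapping domains are an
#'   error.
#' @param global_fold uniform multiplier applied to all mutant chromosomal
#'   signal (default 1).
#' @param depletion_slope per-gene slope linking expression value (a.u.) to
#'   mutant log2 signal loss over the gene body: mutant gene-body signal is
#'   multiplied by `2^(depletion_slope * (expression_value - 5))`. Negative
#'   values deplete transcribed genes; 0 disables the effect.
#' @param n_spike number of spike-in control probes (default 2000; large
#'   enough that the spike-mean scale factor is estimated to a fraction of a
#'   percent).
#' @param spike_noise_sd log2 noise on observed spike-in probes (defaults to
#'   `noise_sd`; 0 makes observed spikes equal their references in both
#'   conditions).
#' @param wt_array_scale,mut_array_scale array-level multiplicative factors
#'   (amplification/hybridization efficiency) applied to every probe of a
#'   condition, spikes included; spike normalization must cancel them.
#' @param seed integer seed; required, all randomness flows from it.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(probe_spacing = 20, noise_sd = 0.25,
                              domains = NULL, global_fold = 1,
                              depletion_slope = 0, n_spike = 2000,
                              spike_noise_sd = noise_sd,
                              wt_array_scale = 1, mut_array_scale = 1,
                              seed) {
  stopifnot(probe_spacing > 0, noise_sd >= 0, global_fold > 0,
            n_spike >= 1, spike_noise_sd >= 0,
            wt_array_scale > 0, mut_array_scale > 0,
            is.numeric(seed), length(seed) == 1L)
  if (!is.null(domains) && nrow(domains) > 0) {
    stopifnot(all(c("chrom", "start", "end", "fold") %in% names(domains)),
              all(domains$fold > 0), all(domains$start < domains$end))
    d <- domains[order(domains$chrom, domains$start), ]
    same <- d$chrom[-1] == d$chrom[-nrow(d)]
    if (any(same & d$start[-1] < d$end[-nrow(d)]))
      stop("planted domains overlap")
  }
  structure(list(probe_spacing = probe_spacing, noise_sd = noise_sd,
                 domains = domains, global_fold = global_fold,
                 depletion_slope = depletion_slope, n_spike = n_spike,
                 spike_noise_sd = spike_noise_sd,
                 wt_array_scale = wt_array_scale,
                 mut_array_scale = mut_array_scale,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate wild-type and mutant probe tracks with spike-in controls
#'
#' Wild-type chromosomal signal is a flat linear baseline of 1.0. Mutant
#' signal is baseline x `global_fold`, x domain fold inside planted domains,
#' x expression-dependent depletion over gene bodies (strand-aware TSS-TES
#' span). Both conditions then receive independent Gaussian log2 noise and
#' their array-level scale factor. Spike-in probes carry their reference
#' values (identical in expectation across conditions) times spike noise and
#' the array scale.
#'
#' @param genome a `genome_model`.
#' @param params a `simulation_params`.
#' @return list with elements `wt` and `mut` (`probe_track`s, linear scale,
#'   spike contig included) and `spikes` (a `spike_in_set`).
#' @export
simulate_probe_tracks <- function(genome, params) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(params, "simulation_params"))
  sp <- params$probe_spacing
  chroms <- genome$chromosomes
  grid <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    pos <- seq(0, chroms$length[i] - sp, by = sp)
    data.frame(chrom = chroms$name[i], pos = pos, stringsAsFactors = FALSE)
  }))
  n <- nrow(grid)

  if (!is.null(params$domains) && nrow(params$domains) > 0) {
    d <- params$domains
    bad <- !(d$chrom %in% chroms$name) |
      d$end > chroms$length[match(d$chrom, chroms$name)] | d$start < 0
    if (any(bad)) stop("planted domain outside the genome")
  }

  truth_wt <- rep(1, n)
  truth_mut <- rep(params$global_fold, n)

  # probes sit on a regular grid, so interval membership is index arithmetic:
  # probes with pos in [s, e) occupy rows offset + (ceiling(s/sp) .. ceiling(e/sp) - 1)
  n_per_chrom <- floor(chroms$length / sp)
  offset <- stats::setNames(cumsum(c(0, n_per_chrom[-length(n_per_chrom)])),
                            chroms$name)
  rows_in <- function(chrom, s, e) {
    i1 <- ceiling(s / sp); i2 <- ceiling(e / sp) - 1
    i2 <- min(i2, n_per_chrom[match(chrom, chroms$name)] - 1)
    if (i2 < i1) return(integer())
    offset[[chrom]] + (i1:i2) + 1L
  }

  if (!is.null(params$domains) && nrow(params$domains) > 0) {
    d <- params$domains
    for (i in seq_len(nrow(d))) {
      idx <- rows_in(d$chrom[i], d$start[i], d$end[i])
      truth_mut[idx] <- truth_mut[idx] * d$fold[i]
    }
  }

  if (params$depletion_slope != 0 && nrow(genome$genes) > 0) {
    g <- genome$genes
    gs <- pmin(g$tss, g$tes); ge <- pmax(g$tss, g$tes)
    dep <- 2^(params$depletion_slope * (g$expression_value - 5))
    for (i in seq_len(nrow(g))) {
      idx <- rows_in(g$chrom[i], gs[i], ge[i])
      truth_mut[idx] <- truth_mut[idx] * dep[i]
    }
  }

  out <- .with_seed(params$seed, {
    refs <- 2^stats::runif(params$n_spike, -2, 2)
    obs_wt <- truth_wt * 2^stats::rnorm(n, 0, params$noise_sd) *
      params$wt_array_scale
    obs_mut <- truth_mut * 2^stats::rnorm(n, 0, params$noise_sd) *
      params$mut_array_scale
    spike_wt <- refs * 2^stats::rnorm(params$n_spike, 0, params$spike_noise_sd) *
      params$wt_array_scale
    spike_mut <- refs * 2^stats::rnorm(params$n_spike, 0, params$spike_noise_sd) *
      params$mut_array_scale
    list(refs = refs, wt = obs_wt, mut = obs_mut,
         spike_wt = spike_wt, spike_mut = spike_mut)
  })

  spike_pos <- (seq_len(params$n_spike) - 1) * sp
  spikes <- spike_in_set(chrom = "spikein", pos = spike_pos,
                         reference = out$refs)
  mk <- function(values, spike_values) {
    probes <- rbind(data.frame(chrom = grid$chrom, pos = grid$pos,
                               value = values, stringsAsFactors = FALSE),
                    data.frame(chrom = "spikein", pos = spike_pos,
                               value = spike_values, stringsAsFactors = FALSE))
    probe_track(probes, scale = "linear", spacing = sp,
                control_chroms = "spikein")
  }
  list(wt = mk(out$wt, out$spike_wt),
       mut = mk(out$mut, out$spike_mut),
       spikes = spikes)
}

#' Spike-in control set
#'
#' Known, condition-invariant reference abundances for the exogenous control
#' probes carried on a virtual contig of a `probe_track` (the analogue of
#' control cDNA diluted into each immunoprecipitated sample before
#' amplification).
#'
#' @param chrom name of the control contig.
#' @param pos probe positions on the control contig.
#' @param reference known reference value per control probe (> 0, linear).
#' @return a `spike_in_set` data.frame.
#' @export
spike_in_set <- function(chrom, pos, reference) {
  stopifnot(all(reference > 0), length(pos) == length(reference))
  structure(data.frame(chrom = chrom, pos = pos, reference = reference,
                       stringsAsFactors = FALSE),
            class = c("spike_in_set", "data.frame"))
}

#' Plant non-overlapping enrichment domains around centromeres
#'
#' Places `n_proximal` domains with midpoints inside the centromere-proximal
#' windows and `n_total - n_proximal` domains on the distal remainder of the
#' chromosome arms. To keep the planted proximal/distal truth unambiguous
#' under probe-level jitter of called-region midpoints, proximal midpoints
#' are kept at least `margin` bp inside the `window` boundary and distal
#' midpoints at least `margin` bp outside it (the even-grid placement adds
#' about half a grid step of further guard). Domains are mutually separated
#' by at least `min_spacing` centre-to-centre and avoid centromere bodies
#' and chromosome ends.
#'
#' @param genome a `genome_model`.
#' @param n_total total number of domains.
#' @param n_proximal how many must be centromere-proximal by midpoint.
#' @param width domain width in bp (default 2000).
#' @param fold linear enrichment fold (default 6).
#' @param window proximity window from centromere edges in bp (default
#'   100 kb).
#' @param min_spacing minimum centre-to-centre distance in bp (default
#'   6 kb).
#' @param margin guard distance from the `window` boundary in bp (default
#'   500; the 100 kb flanks barely hold 96 domains at 6 kb spacing, so the
#'   explicit guard must stay small).
#' @param seed integer seed.
#' @return data.frame of domains (`chrom`, `start`, `end`, `fold`,
#'   `proximal`) suitable for [simulation_params()].
#' @export
plant_domains <- function(genome, n_total, n_proximal, width = 2000,
                          fold = 6, window = 100000, min_spacing = 6000,
                          margin = 500, seed) {
  stopifnot(n_proximal <= n_total, width > 0, fold > 0,
            min_spacing >= width, margin >= 0, margin < window)
  chroms <- genome$chromosomes
  cen <- genome$centromeres

  # candidate midpoint intervals [lo, hi) per zone
  zones <- function(proximal) {
    out <- list()
    for (i in seq_len(nrow(cen))) {
      ci <- cen[i, ]
      len <- chroms$length[chroms$name == ci$chrom]
      if (proximal) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ci$chrom,
          lo = c(ci$start - window + margin, ci$end),
          hi = c(ci$start, ci$end + window - margin))
      } else {
        out[[length(out) + 1]] <- data.frame(
          chrom = ci$chrom,
          lo = c(width, ci$end + window + margin),
          hi = c(ci$start - window - margin, len - width))
      }
    }
    z <- do.call(rbind, out)
    z$lo <- pmax(z$lo, width / 2)
    z[z$hi - z$lo > min_spacing, ]
  }

  place <- function(z, k) {
    # spread k midpoints over the zones proportionally to zone length, then
    # place on an even grid with jitter small enough that min_spacing holds
    # by construction (grid cells also leave half a step at zone edges, so
    # cross-zone spacing is >= step as well)
    if (k == 0) return(NULL)
    zlen <- z$hi - z$lo
    quota <- k * zlen / sum(zlen)
    nk <- floor(quota); rem <- k - sum(nk)
    if (rem > 0) {
      ord <- order(quota - nk, decreasing = TRUE)
      nk[ord[seq_len(rem)]] <- nk[ord[seq_len(rem)]] + 1
    }
    rows <- list()
    for (j in seq_len(nrow(z))) {
      if (nk[j] == 0) next
      step <- zlen[j] / nk[j]
      if (step < min_spacing)
        stop("cannot place ", k, " domains with min_spacing ", min_spacing)
      jit <- max(0, min(200, (step - min_spacing) / 2 - 1))
      mids <- z$lo[j] + (seq_len(nk[j]) - 0.5) * step +
        stats::runif(nk[j], -jit, jit)
      rows[[length(rows) + 1]] <- data.frame(chrom = z$chrom[j],
                                             mid = floor(mids),
                                             stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  d <- .with_seed(seed, {
    prox <- place(zones(TRUE), n_proximal)
    dist <- place(zones(FALSE), n_total - n_proximal)
    prox$proximal <- TRUE
    if (!is.null(dist) && nrow(dist) > 0) dist$proximal <- FALSE
    rbind(prox, dist)
  })
  d$start <- d$mid - floor(width / 2)
  d$end <- d$start + width
  d$fold <- fold
  d <- d[order(d$chrom, d$start), c("chrom", "start", "end", "fold",
                                    "proximal")]
  rownames(d) <- NULL
  d
}

#' Simulate replicate percent-input qPCR measurements
#'
#' Replicates are the true %IP value times lognormal multiplicative noise
#' with the requested coefficient of variation, emulating biological
#' replicate scatter.
#'
#' @param true_percent_ip true enrichment in percent of input, in (0, 100].
#' @param n_replicates number of replicates (>= 1; 3 is the usual design).
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param seed integer seed.
#' @param locus,antibody labels carried into the sample.
#' @return a `qpcr_sample` (see [qpcr_sample()]).
#' @export
simulate_qpcr <- function(true_percent_ip, n_replicates = 3, cv = 0.05,
                          seed, locus = "locus", antibody = "antibody") {
  stopifnot(n_replicates >= 1, cv >= 0)
  if (!is.numeric(true_percent_ip) || true_percent_ip <= 0 ||
      true_percent_ip > 100)
    stop("true_percent_ip must lie in (0, 100]")
  vals <- .with_seed(seed, {
    if (cv == 0) rep(true_percent_ip, n_replicates)
    else {
      sdlog <- sqrt(log(1 + cv^2))
      true_percent_ip * stats::rlnorm(n_replicates,
                                      meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  })
  qpcr_sample(locus = locus, antibody = antibody, values = vals)
}
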