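#' Fraction of the genome within a window of centromere edges
#'
#' Total length of the flanking intervals extending `window` bp outward from
#' each centromere edge — clipped to chromosome bounds, centromere bodies
#' excluded — divided by the total genome length. On the default fixture
#' (three centromeres, 100 kb flanks, 12.57 Mb genome) this is
#' 600,000 / 12,570,000, i.e. the published "4.8% of the genome".
#'
#' @param genome a `genome_model`.
#' @param window flank width in bp (default 100 kb).
#' @return the genome fraction in [0, 1].
#' @export
proximal_genome_fraction <- function(genome, window = 100000) {
  stopifnot(inherits(genome, "genome_model"), window >= 0)
  if (window == 0) return(0)
  lens <- stats::setNames(genome$chromosomes$length,
                          genome$chromosomes$name)
  cen <- genome$centromeres
  cen_gr <- GenomicRanges::GRanges(
    cen$chrom, IRanges::IRanges(start = cen$start + 1, end = cen$end))
  flank <- c(GenomicRanges::flank(cen_gr, window, start = TRUE),
             GenomicRanges::flank(cen_gr, window, start = FALSE))
  flank <- GenomicRanges::trim(GenomicRanges::GRanges(
    GenomicRanges::seqnames(flank),
    IRanges::IRanges(pmax(GenomicRanges::start(flank), 1),
                     pmin(GenomicRanges::end(flank),
                          lens[as.character(GenomicRanges::seqnames(flank))]))))
  flank <- GenomicRanges::reduce(flank)
  flank <- GenomicRanges::setdiff(flank, cen_gr)
  sum(GenomicRanges::width(flank)) / sum(lens)
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items without
#' replacement from a population of `N` of which `K` are marked. Evaluated
#' in log space so that tails around 1e-80 are representable.
#'
#' @param k observed number of marked draws.
#' @param n number of draws.
#' @param K marked population size.
#' @param N population size.
#' @param log10_p if `TRUE` return log10 of the tail probability.
#' @return the tail probability (or its log10).
#' @export
hypergeometric_tail <- function(k, n, K, N, log10_p = FALSE) {
  stopifnot(k >= 0, n >= 0, K >= 0, N >= 0, k <= n, n <= N, K <= N)
  if (k == 0) return(if (log10_p) 0 else 1)
  lp <- stats::phyper(k - 1, m = K, n = N - K, k = n,
                      lower.tail = FALSE, log.p = TRUE)
  if (log10_p) lp / log(10) else exp(lp)
}

#' Test centromere-proximal enrichment of called regions
#'
#' A region is proximal when its midpoint lies within `window` bp of a
#' centromere edge (midpoints inside a centromere count as distance 0). The
#' hypergeometric population is the genome tiled into `bin_size` bins
#' outside centromere bodies: `N` bins in total, `K` of them proximal by
#' their own midpoints; drawing the `n` observed regions and seeing `k`
#' proximal ones yields the upper-tail p-value.
#'
#' @param regions an `enriched_regions` data.frame (non-empty).
#' @param genome a `genome_model`.
#' @param window proximity window in bp (default 100 kb).
#' @param bin_size population bin size in bp (default 1 kb, the minimum
#'   region length).
#' @return a `proximity_enrichment` list: `n_regions`, `k_proximal`,
#'   `proportion`, `genome_fraction`, `p_value`, `log10_p`, `N`, `K`,
#'   `window`, `bin_size`.
#' @export
test_proximity_enrichment <- function(regions, genome, window = 100000,
                                      bin_size = 1000) {
  stopifnot(inherits(genome, "genome_model"), window >= 0, bin_size > 0)
  if (is.null(regions) || nrow(regions) == 0)
    stop("no regions to test")
  mids <- (regions$start + regions$end) / 2
  prox <- .point_is_proximal(mids, regions$chrom, genome, window)
  k <- sum(prox); n <- nrow(regions)

  pop <- .bin_population(genome, window, bin_size)
  p <- hypergeometric_tail(k, n, pop$K, pop$N)
  lp <- hypergeometric_tail(k, n, pop$K, pop$N, log10_p = TRUE)
  structure(list(n_regions = n, k_proximal = k, proportion = k / n,
                 genome_fraction = proximal_genome_fraction(genome, window),
                 p_value = p, log10_p = lp, N = pop$N, K = pop$K,
                 window = window, bin_size = bin_size),
            class = "proximity_enrichment")
}

# TRUE for points within `window` of a centromere edge on their chromosome
# (equivalently: inside [cen_start - window, cen_end + window))
.point_is_proximal <- function(pos, chrom, genome, window) {
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(genome$centromeres))) {
    ci <- genome$centromeres[i, ]
    hit <- chrom == ci$chrom & pos >= ci$start - window &
      pos < ci$end + window
    out <- out | hit
  }
  out
}

# hypergeometric population: bin_size bins tiling each chromosome, kept when
# the bin midpoint falls outside every centromere body; K of them proximal
.bin_population <- function(genome, window, bin_size) {
  N <- 0L; K <- 0L
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    mids <- seq(bin_size / 2, len, by = bin_size)
    cen <- genome$centromeres[genome$centromeres$chrom == ch, ]
    in_cen <- rep(FALSE, length(mids))
    for (j in seq_len(nrow(cen)))
      in_cen <- in_cen | (mids >= cen$start[j] & mids < cen$end[j])
    mids <- mids[!in_cen]
    N <- N + length(mids)
    K <- K + sum(.point_is_proximal(mids, rep(ch, length(mids)), genome,
                                    window))
  }
  list(N = N, K = K)
}

#' @export
print.proximity_enrichment <- function(x, ...) {
  cat(sprintf(
    "proximity_enrichment: %d/%d regions proximal (%.1f%%) vs %.1f%% of genome; log10 p = %.1f\n",
    x$k_proximal, x$n_regions, 100 * x$proportion,
    100 * x$genome_fraction, x$log10_p))
  invisible(x)
}
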