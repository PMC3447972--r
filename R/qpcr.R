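#' Percent-input ChIP enrichment
#'
#' The standard %IP definition: the immunoprecipitated template quantity as
#' a percentage of the (dilution-corrected) input template quantity,
#' `100 * ip / (input * input_dilution_factor)`. When the input was
#' quantified on a dilution, the dilution factor scales it back to the full
#' input.
#'
#' @param ip_quantity template quantity measured in the IP (> 0).
#' @param input_quantity template quantity measured in the input (> 0).
#' @param input_dilution_factor fold dilution of the measured input
#'   (>= 1; default 1).
#' @return %IP; values above 100 are reported but flagged with a warning
#'   (they indicate a quantification or dilution bookkeeping error).
#' @export
percent_ip <- function(ip_quantity, input_quantity,
                       input_dilution_factor = 1) {
  if (any(ip_quantity <= 0) || any(input_quantity <= 0))
    stop("template quantities must be positive")
  if (any(input_dilution_factor < 1))
    stop("input_dilution_factor must be >= 1")
  pct <- 100 * ip_quantity / (input_quantity * input_dilution_factor)
  if (any(pct > 100))
    warning("%IP above 100%: check input dilution bookkeeping")
  pct
}

#' Replicate ChIP-qPCR sample
#'
#' Bundles replicate %IP measurements for one locus/antibody with their
#' summary statistics (mean and n-1 standard deviation, the published
#' error-bar convention for biological replicates).
#'
#' @param locus locus label.
#' @param antibody antibody label.
#' @param values replicate %IP values in [0, 100].
#' @return a `qpcr_sample` list with `locus`, `antibody`, `values`, `mean`,
#'   `sd` (`NA` with a single replicate) and `n`.
#' @export
qpcr_sample <- function(locus, antibody, values) {
  if (length(values) < 1) stop("at least one replicate is required")
  if (any(values < 0 | values > 100))
    stop("%IP replicate values must lie in [0, 100]")
  s <- summarize_replicates(values)
  structure(list(locus = locus, antibody = antibody, values = values,
                 mean = s[["mean"]], sd = s[["sd"]], n = length(values)),
            class = "qpcr_sample")
}

#' Mean and standard deviation of replicate measurements
#'
#' @param values numeric vector of replicate values (>= 1).
#' @return named numeric vector `c(mean, sd)`; `sd` is the n-1 sample
#'   standard deviation and is `NA` (undefined) for a single replicate,
#'   with a warning.
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0) stop("no replicate values")
  m <- mean(values)
  if (length(values) == 1) {
    warning("single replicate: standard deviation undefined")
    return(c(mean = m, sd = NA_real_))
  }
  c(mean = m, sd = stats::sd(values))
}

#' Relative enrichment between two qPCR samples
#'
#' Ratio of the two sample means (ratio-of-means, matching how a relative
#' enrichment bar is formed from two plotted means). A value of 0.25 reads
#' as "four-fold less" enrichment at `a` than at `b`.
#'
#' @param a,b `qpcr_sample` objects; `b` is the denominator.
#' @return the ratio `a$mean / b$mean`.
#' @export
relative_enrichment <- function(a, b) {
  stopifnot(inherits(a, "qpcr_sample"), inherits(b, "qpcr_sample"))
  if (b$mean <= 0) stop("denominator sample mean must be positive")
  a$mean / b$mean
}

#' @export
print.qpcr_sample <- function(x, ...) {
  cat(sprintf("qpcr_sample %s/%s: mean %.3g%% IP, sd %.3g (n=%d)\n",
              x$locus, x$antibody, x$mean, x$sd, x$n))
  invisible(x)
}
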