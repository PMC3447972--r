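#' Expression class of a gene
#'
#' The five-category scale over expression values in arbitrary units (a.u.,
#' 5-15): very_low below 8, low in [8, 10), medium in [10, 12), high in
#' [12, 14], very_high above 14. Interior boundaries are lower-inclusive;
#' the value 14 belongs to high, matching the published "(>14)" and "(<8)"
#' endpoints.
#'
#' @param value numeric vector of expression values (finite).
#' @return character vector of class labels.
#' @export
classify_expression <- function(value) {
  if (!all(is.finite(value))) stop("expression values must be finite")
  out <- character(length(value))
  out[value < 8] <- "very_low"
  out[value >= 8 & value < 10] <- "low"
  out[value >= 10 & value < 12] <- "medium"
  out[value >= 12 & value <= 14] <- "high"
  out[value > 14] <- "very_high"
  out
}

#' Ordered expression class labels, lowest to highest
#' @export
expression_class_levels <- function() {
  c("very_low", "low", "medium", "high", "very_high")
}

#' TSS-aligned per-gene signal matrix
#'
#' Extracts, for every gene, the track signal in a window around its
#' transcription start site, oriented in the direction of transcription
#' (minus-strand genes are reversed so positive positions point downstream).
#' The window is cut into `bin`-bp bins whose values are the mean of member
#' probes; bins containing no probe are `NA`. Genes whose window would
#' extend beyond their chromosome are skipped with a warning.
#'
#' @param track a `probe_track` (any scale; values are used as-is).
#' @param genes gene annotation data.frame (`chrom`, `strand`, `tss`, ...).
#' @param upstream,downstream window extent in bp on either side of the TSS.
#' @param bin bin width in bp; must divide `upstream + downstream`.
#' @return a genes x bins matrix with `rownames` from `genes$id` and column
#'   names the bin-start offsets relative to the TSS; attribute `positions`
#'   holds the numeric offsets.
#' @export
tss_aligned_matrix <- function(track, genes, upstream = 500,
                               downstream = 2000, bin = 20) {
  stopifnot(inherits(track, "probe_track"), upstream >= 0, downstream > 0,
            bin > 0)
  if ((upstream + downstream) %% bin != 0)
    stop("bin must divide the window extent")
  n_bins <- (upstream + downstream) / bin
  positions <- seq(-upstream, downstream - bin, by = bin)

  chrom_len <- vapply(split(track$pos, track$chrom), max, numeric(1))
  chrom_idx <- split(seq_len(nrow(track)), track$chrom)
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins,
                dimnames = list(genes$id, positions))
  skipped <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lo <- if (g$strand == "+") g$tss - upstream else g$tss - downstream
    hi <- lo + upstream + downstream
    if (lo < 0 || hi > chrom_len[[g$chrom]] + track_spacing(track)) {
      skipped <- c(skipped, g$id)
      next
    }
    ci <- chrom_idx[[g$chrom]]
    pos_ch <- track$pos[ci]
    i1 <- findInterval(lo - 1e-9, pos_ch) + 1  # first probe with pos >= lo
    i2 <- findInterval(hi - 1e-9, pos_ch)      # last probe with pos < hi
    if (i2 < i1) next
    p <- pos_ch[i1:i2]; v <- track$value[ci[i1:i2]]
    # minus strand: reflect probe intervals so downstream is transcription
    # direction; the TSS coordinate of a minus gene is its exclusive bound
    off <- if (g$strand == "+") p - g$tss else g$tss - p - track_spacing(track)
    # offsets in [-upstream, downstream); bin index by floor division
    bi <- floor((off + upstream) / bin) + 1
    ok <- bi >= 1 & bi <= n_bins
    sums <- tapply(v[ok], bi[ok], mean)
    row <- rep(NA_real_, n_bins)
    row[as.integer(names(sums))] <- as.numeric(sums)
    mat[i, ] <- row
  }
  if (length(skipped))
    warning(length(skipped), " gene(s) skipped: window exceeds chromosome (",
            paste(utils::head(skipped, 3), collapse = ", "),
            if (length(skipped) > 3) ", ..." else "", ")")
  attr(mat, "positions") <- positions
  mat
}

#' Expression-stratified metagene profile with confidence intervals
#'
#' Averages TSS-aligned per-gene signal vectors within each expression
#' class and attaches two-sided Student-t confidence interval half-widths
#' per position (99% by default, the published error-bar convention).
#' Classes with no genes are dropped with a warning; positions where a
#' class has fewer than 2 non-missing genes get an `NA` half-width.
#'
#' @param mat genes x positions matrix from [tss_aligned_matrix()].
#' @param classes character vector of class labels, one per matrix row.
#' @param ci_level two-sided confidence level (default 0.99).
#' @return a `metagene_profile` data.frame with columns `class`, `position`,
#'   `n`, `mean`, `ci_half_width`; classes ordered low to high expression.
#' @export
metagene_profile <- function(mat, classes, ci_level = 0.99) {
  stopifnot(is.matrix(mat), length(classes) == nrow(mat),
            ci_level > 0, ci_level < 1)
  positions <- attr(mat, "positions")
  if (is.null(positions)) positions <- as.numeric(colnames(mat))
  levels_present <- intersect(expression_class_levels(), unique(classes))
  missing_classes <- setdiff(unique(classes), levels_present)
  empty <- setdiff(expression_class_levels(), classes)
  if (length(empty))
    warning("empty class(es) excluded: ", paste(empty, collapse = ", "))

  alpha <- 1 - ci_level
  rows <- list()
  for (cl in levels_present) {
    sub <- mat[classes == cl, , drop = FALSE]
    n_tot <- nrow(sub)
    n_pos <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    mu[n_pos == 0] <- NA_real_
    sdv <- apply(sub, 2, stats::sd, na.rm = TRUE)
    hw <- ifelse(n_pos >= 2,
                 stats::qt(1 - alpha / 2, df = pmax(n_pos - 1, 1)) *
                   sdv / sqrt(n_pos),
                 NA_real_)
    rows[[cl]] <- data.frame(class = cl, position = positions, n = n_tot,
                             mean = unname(mu), ci_half_width = unname(hw),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Moving-average occupancy versus expression curve
#'
#' Sorts genes by expression value and slides a window of `window` genes in
#' steps of `step`, reporting the mean expression and mean occupancy of each
#' window (the "window size = 100, step size = 1" display). With `n` genes
#' and step 1 the curve has `n - window + 1` points.
#'
#' @param gene_values per-gene occupancy summary (e.g. mean gene-body log2
#'   ratio).
#' @param expression per-gene expression values (a.u.), same length.
#' @param window window size in genes (default 100).
#' @param step step size in genes (default 1).
#' @return data.frame with columns `mean_expression` and `mean_occupancy`.
#' @export
occupancy_vs_expression <- function(gene_values, expression, window = 100,
                                    step = 1) {
  stopifnot(length(gene_values) == length(expression), window >= 1,
            step >= 1)
  n <- length(gene_values)
  if (n < window)
    stop("need at least ", window, " genes for a window of ", window)
  ord <- order(expression)
  e <- expression[ord]; v <- gene_values[ord]
  starts <- seq(1, n - window + 1, by = step)
  cs_e <- cumsum(c(0, e)); cs_v <- cumsum(c(0, v))
  data.frame(
    mean_expression = (cs_e[starts + window] - cs_e[starts]) / window,
    mean_occupancy = (cs_v[starts + window] - cs_v[starts]) / window)
}

#' Mean signal over each gene body
#'
#' Convenience summary feeding [occupancy_vs_expression()] and the class
#' ordering checks: the mean track value over each gene's TSS-TES span
#' (strand-aware). Genes whose span contains no probe get `NA`.
#'
#' @param track a `probe_track`.
#' @param genes gene annotation data.frame.
#' @return numeric vector, one value per gene.
#' @export
gene_body_means <- function(track, genes) {
  stopifnot(inherits(track, "probe_track"))
  out <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    sel <- which(track$chrom == ch)
    pos <- track$pos[sel]; val <- track$value[sel]
    gi <- which(genes$chrom == ch)
    gs <- pmin(genes$tss[gi], genes$tes[gi])
    ge <- pmax(genes$tss[gi], genes$tes[gi])
    i1 <- findInterval(gs - 1e-9, pos) + 1   # first probe with pos >= gs
    i2 <- findInterval(ge - 1e-9, pos)       # last probe with pos < ge
    cs <- cumsum(c(0, val))
    ok <- i2 >= i1
    out[gi[ok]] <- (cs[i2[ok] + 1] - cs[i1[ok]]) / (i2[ok] - i1[ok] + 1)
  }
  out
}
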