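#' Synthetic genome model
#'
#' A `genome_model` is the coordinate frame for the whole pipeline: a small
#' set of chromosomes with one centromere each, subtelomeric intervals at the
#' chromosome ends, and expression-annotated genes. All coordinates are
#' 0-based half-open (BED convention); GFF3 output converts to 1-based closed
#' at the file boundary.
#'
#' The default fixture mimics the scale of the fission yeast genome: three
#' chromosomes of 5.58, 4.54 and 2.45 Mb (12.57 Mb total) with centromeres of
#' 40, 65 and 110 kb near the chromosome midpoints, so that the 100 kb flanks
#' on either side of the three centromeres cover ~4.8% of the genome.
#'
#' @name genome_model
NULL

#' Default fixture parameters for the synthetic genome
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param centromere_spans named integer vector of centromere widths (bp),
#'   one per chromosome; each centromere is centred on its chromosome.
#' @param subtelomere_length length (bp) of the subtelomeric interval at each
#'   chromosome end.
#' @param n_genes total number of genes to tile across the chromosome arms.
#' @param class_proportions expected number of genes per expression class on
#'   the five-class scale, ordered very_low, low, medium, high, very_high.
#'   The defaults reproduce the published class sizes 815:1904:1726:591:37.
#' @param min_gene_length smallest admissible gene length (bp); packing that
#'   would force genes below this length is an error.
#' @return a list of fixture parameters for [build_genome_model()].
#' @export
genome_config <- function(chrom_lengths = c(chr1 = 5580000, chr2 = 4540000,
                                            chr3 = 2450000),
                          centromere_spans = c(chr1 = 40000, chr2 = 65000,
                                               chr3 = 110000),
                          subtelomere_length = 50000,
                          n_genes = 5073,
                          class_proportions = c(very_low = 815, low = 1904,
                                                medium = 1726, high = 591,
                                                very_high = 37),
                          min_gene_length = 300) {
  stopifnot(length(chrom_lengths) >= 1,
            all(chrom_lengths > 0),
            identical(names(chrom_lengths), names(centromere_spans)),
            all(centromere_spans < chrom_lengths),
            subtelomere_length >= 0,
            n_genes >= 0,
            length(class_proportions) == 5L,
            all(class_proportions >= 0),
            min_gene_length > 0)
  list(chrom_lengths = chrom_lengths,
       centromere_spans = centromere_spans,
       subtelomere_length = subtelomere_length,
       n_genes = n_genes,
       class_proportions = class_proportions,
       min_gene_length = min_gene_length)
}

#' Build the synthetic genome model
#'
#' Chromosome arms (the intervals flanking each centromere) are partitioned
#' into equal slots, one gene per slot, and each gene occupies a seeded
#' random fraction of its slot so genes never overlap each other or the
#' centromere. Expression classes are assigned at exactly the calibrated
#' per-class counts (scaled from the published 815:1904:1726:591:37 split)
#' and expression values are drawn uniformly within each class interval on
#' the 5-15 arbitrary-unit scale.
#'
#' @param config fixture parameters from [genome_config()].
#' @param seed integer seed; the model is a deterministic function of
#'   `(config, seed)`.
#' @return a `genome_model`: list with `chromosomes` (data.frame name,
#'   length), `centromeres`, `subtelomeres` (data.frames chrom, start, end;
#'   0-based half-open) and `genes` (data.frame id, chrom, strand, tss, tes,
#'   expression_value, expression_class).
#' @export
build_genome_model <- function(config = genome_config(), seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  chroms <- data.frame(name = names(config$chrom_lengths),
                       length = unname(as.numeric(config$chrom_lengths)),
                       stringsAsFactors = FALSE)

  cen <- do.call(rbind, lapply(chroms$name, function(ch) {
    len <- chroms$length[chroms$name == ch]
    span <- config$centromere_spans[[ch]]
    mid <- floor(len / 2)
    start <- mid - floor(span / 2)
    data.frame(chrom = ch, start = start, end = start + span,
               stringsAsFactors = FALSE)
  }))

  st_len <- config$subtelomere_length
  subtel <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    data.frame(chrom = rep(chroms$name[i], 2L),
               start = c(0, len - st_len),
               end = c(st_len, len),
               stringsAsFactors = FALSE)
  }))
  if (st_len == 0) subtel <- subtel[0, ]

  genes <- .tile_genes(chroms, cen, config, seed)

  model <- structure(list(chromosomes = chroms, centromeres = cen,
                          subtelomeres = subtel, genes = genes),
                     class = "genome_model")
  validate_genome_model(model)
  model
}

# Deterministic gene tiling: arms get genes proportional to length, each arm
# is cut into equal slots, one gene per slot at a jittered offset.
.tile_genes <- function(chroms, cen, config, seed) {
  empty <- data.frame(id = character(), chrom = character(),
                      strand = character(), tss = numeric(), tes = numeric(),
                      expression_value = numeric(),
                      expression_class = character(),
                      stringsAsFactors = FALSE)
  n_genes <- config$n_genes
  if (n_genes == 0) return(empty)

  arms <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    ch <- chroms$name[i]
    ci <- cen[cen$chrom == ch, ]
    data.frame(chrom = ch,
               start = c(0, ci$end),
               end = c(ci$start, chroms$length[i]),
               stringsAsFactors = FALSE)
  }))
  arms$len <- arms$end - arms$start

  # largest-remainder apportionment of genes to arms
  quota <- n_genes * arms$len / sum(arms$len)
  n_arm <- floor(quota)
  rem <- n_genes - sum(n_arm)
  if (rem > 0) {
    ord <- order(quota - n_arm, decreasing = TRUE)
    n_arm[ord[seq_len(rem)]] <- n_arm[ord[seq_len(rem)]] + 1L
  }
  slot <- ifelse(n_arm > 0, arms$len / n_arm, Inf)
  if (any(slot < config$min_gene_length / 0.8)) {
    stop("infeasible gene packing: ", n_genes,
         " genes leave arm slots below the minimum gene length")
  }

  withr_seed <- .with_seed(seed, {
    rows <- vector("list", nrow(arms))
    for (a in seq_len(nrow(arms))) {
      na <- n_arm[a]
      if (na == 0) next
      sl <- arms$len[a] / na
      frac <- stats::runif(na, 0.45, 0.8)      # gene fills this slot fraction
      off <- stats::runif(na, 0, 1 - frac - 0.05)
      gs <- floor(arms$start[a] + (seq_len(na) - 1 + off) * sl)
      ge <- pmin(floor(gs + frac * sl), arms$end[a])
      strand <- sample(c("+", "-"), na, replace = TRUE)
      rows[[a]] <- data.frame(chrom = arms$chrom[a], start = gs, end = ge,
                              strand = strand, stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows)

    # exact calibrated class counts, shuffled over genes
    counts <- .apportion_classes(config$class_proportions, nrow(g))
    labels <- rep(names(counts), counts)
    labels <- sample(labels)
    g$expression_class <- labels
    g$expression_value <- .draw_expression(labels)
    g
  })
  g <- withr_seed

  g <- g[order(match(g$chrom, chroms$name), g$start), ]
  plus <- g$strand == "+"
  data.frame(id = sprintf("gene%04d", seq_len(nrow(g))),
             chrom = g$chrom,
             strand = g$strand,
             tss = ifelse(plus, g$start, g$end),
             tes = ifelse(plus, g$end, g$start),
             expression_value = g$expression_value,
             expression_class = g$expression_class,
             stringsAsFactors = FALSE)
}

# largest-remainder apportionment of n over the five class proportions
.apportion_classes <- function(props, n) {
  quota <- n * props / sum(props)
  cnt <- floor(quota)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(quota - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(cnt), names(props))
}

# uniform draw within each class interval on the published 5-15 a.u. scale
.draw_expression <- function(labels) {
  lo <- c(very_low = 5, low = 8, medium = 10, high = 12, very_high = 14)
  hi <- c(very_low = 8, low = 10, medium = 12, high = 14, very_high = 15)
  v <- stats::runif(length(labels), lo[labels], hi[labels])
  # keep draws off the class boundaries that belong to the neighbour class
  vl <- labels == "very_low";  v[vl] <- pmin(v[vl], 8 - 1e-9)
  md <- labels == "medium";    v[md] <- pmin(v[md], 12 - 1e-9)
  lw <- labels == "low";       v[lw] <- pmin(v[lw], 10 - 1e-9)
  vh <- labels == "very_high"; v[vh] <- pmax(v[vh], 14 + 1e-9)
  unname(v)
}

# evaluate expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Validate a genome model's invariants
#'
#' Checks that every interval lies within its chromosome, centromeres are
#' disjoint with exactly one per chromosome, genes avoid centromere bodies,
#' expression values sit in [5, 15] and agree with their class under
#' [classify_expression()], and strand orientation matches tss/tes order.
#'
#' @param model a `genome_model`.
#' @return the model, invisibly; errors describe the violated invariant.
#' @export
validate_genome_model <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  chroms <- model$chromosomes
  lens <- stats::setNames(chroms$length, chroms$name)
  chk_iv <- function(df, what) {
    if (nrow(df) == 0) return(invisible())
    if (!all(df$chrom %in% chroms$name))
      stop(what, ": unknown chromosome")
    if (!all(df$start >= 0 & df$end <= lens[df$chrom] & df$start < df$end))
      stop(what, ": interval outside chromosome bounds")
  }
  chk_iv(model$centromeres, "centromeres")
  chk_iv(model$subtelomeres, "subtelomeres")
  if (anyDuplicated(model$centromeres$chrom))
    stop("centromeres: more than one per chromosome")
  if (nrow(model$centromeres) != nrow(chroms))
    stop("centromeres: expected one per chromosome")

  g <- model$genes
  if (nrow(g) > 0) {
    gs <- pmin(g$tss, g$tes); ge <- pmax(g$tss, g$tes)
    if (!all(gs >= 0 & ge <= lens[g$chrom]))
      stop("genes: span outside chromosome bounds")
    plus <- g$strand == "+"
    if (!all(plus | g$strand == "-")) stop("genes: strand must be + or -")
    if (!all(g$tss[plus] < g$tes[plus]) || !all(g$tss[!plus] > g$tes[!plus]))
      stop("genes: tss/tes order inconsistent with strand")
    if (!all(g$expression_value >= 5 & g$expression_value <= 15))
      stop("genes: expression value outside [5, 15]")
    if (!all(g$expression_class == classify_expression(g$expression_value)))
      stop("genes: expression class inconsistent with value")
    for (i in seq_len(nrow(model$centromeres))) {
      ci <- model$centromeres[i, ]
      on_ch <- g$chrom == ci$chrom
      if (any(gs[on_ch] < ci$end & ge[on_ch] > ci$start))
        stop("genes: gene overlaps a centromere")
    }
  }
  invisible(model)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp;",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Distance from each gene to the nearest centromere edge
#'
#' Edge-based distance: the number of bases between the gene's closest
#' coordinate and the nearest centromere boundary on the same chromosome
#' (0 if the gene touches a centromere). Genes on chromosomes without a
#' centromere get `Inf`.
#'
#' @param genome a `genome_model`.
#' @param genes optional gene data.frame (defaults to `genome$genes`).
#' @return numeric vector of distances, one per gene.
#' @export
gene_centromere_distance <- function(genome, genes = genome$genes) {
  if (nrow(genes) == 0) return(numeric())
  gs <- pmin(genes$tss, genes$tes); ge <- pmax(genes$tss, genes$tes)
  d <- rep(Inf, nrow(genes))
  for (i in seq_len(nrow(genome$centromeres))) {
    ci <- genome$centromeres[i, ]
    on_ch <- genes$chrom == ci$chrom
    gap <- pmax(0, pmax(ci$start - ge[on_ch], gs[on_ch] - ci$end))
    d[on_ch] <- pmin(d[on_ch], gap)
  }
  d
}

#' Genes within a distance of the nearest centromere
#'
#' Selects genes whose span lies within `distance` bp of the nearest
#' centromere edge (boundary inclusive, edge-based distance). With
#' `distance = 0` only genes abutting or touching a centromere interval
#' qualify.
#'
#' @param genome a `genome_model`.
#' @param distance maximum distance in bp (default 100 kb, the window used
#'   for the centromere-proximal gene selection).
#' @return the qualifying subset of `genome$genes`.
#' @export
proximal_gene_subset <- function(genome, distance = 100000) {
  stopifnot(distance >= 0)
  d <- gene_centromere_distance(genome)
  genome$genes[d <= distance, , drop = FALSE]
}
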