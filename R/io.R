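#' Read and write probe tracks as bedGraph
#'
#' Tracks travel as 4-column bedGraph (0-based half-open intervals of one
#' probe spacing each). Because bedGraph carries no scale, the scale and
#' spacing are recorded in a flat key-value sidecar file `<path>.meta`
#' written next to the track; `read_track()` uses it when present, and an
#' explicitly `declared_scale` always wins.
#'
#' @param path bedGraph file path.
#' @param declared_scale `"linear"` or `"log2"`; overrides the sidecar.
#' @param spacing probe spacing in bp; inferred from the first record when
#'   absent from sidecar and arguments.
#' @return a `probe_track`.
#' @export
read_track <- function(path, declared_scale = NULL, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty track file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) {
                   .locate_bad_bedgraph_line(path)
                   stop("malformed bedGraph in ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (length(gr) == 0) stop("empty track file: ", path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   value = gr$score, stringsAsFactors = FALSE)
  # preserve file order for line-number diagnostics
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    bad <- i[which(diff(df$start[i]) <= 0) + 1]
    if (length(bad))
      stop("unsorted or duplicate interval at line ", bad[1], " of ", path)
    ov <- i[which(df$start[i][-1] < df$end[i][-length(i)]) + 1]
    if (length(ov))
      stop("overlapping intervals at line ", ov[1], " of ", path)
  }

  meta <- .read_sidecar(paste0(path, ".meta"))
  scale <- declared_scale %||% meta$scale %||% "linear"
  spacing <- spacing %||% .num_or_null(meta$spacing) %||%
    (df$end[1] - df$start[1])
  ctrl <- if (!is.null(meta$control_chroms) && nzchar(meta$control_chroms))
    strsplit(meta$control_chroms, ",", fixed = TRUE)[[1]] else character()
  probe_track(data.frame(chrom = df$chrom, pos = df$start, value = df$value,
                         stringsAsFactors = FALSE),
              scale = scale, spacing = spacing, control_chroms = ctrl)
}

# scan a bedGraph for the first structurally bad line and error naming it
.locate_bad_bedgraph_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "track") || startsWith(ln, "#")) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) != 4 || anyNA(suppressWarnings(as.numeric(f[2:4]))))
      stop("malformed bedGraph line ", i, " in ", path, ": '", ln, "'",
           call. = FALSE)
  }
  invisible()
}

#' @rdname read_track
#' @param track a `probe_track` to write.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "probe_track"))
  sp <- track_spacing(track)
  gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(start = track$pos + 1, end = track$pos + sp),
    score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  .write_sidecar(paste0(path, ".meta"),
                 list(scale = track_scale(track), spacing = sp,
                      control_chroms = paste(control_chroms(track),
                                             collapse = ",")))
  invisible(path)
}

#' Read and write called regions as BED5
#'
#' Regions are written as BED5: name is the region index, score is
#' `mean_fold * 100` rounded (probe counts are not representable in BED5
#' and are dropped on write).
#'
#' @param path BED file path.
#' @return for `read_regions`, a data.frame `chrom`, `start`, `end`,
#'   `name`, `mean_fold` (score / 100).
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED record with end <= start in ", path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               as.character(seq_along(gr)),
             mean_fold = if (!is.null(gr$score)) gr$score / 100 else
               NA_real_,
             stringsAsFactors = FALSE)
}

#' @rdname read_regions
#' @param regions an `enriched_regions` data.frame.
#' @export
write_regions <- function(regions, path) {
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(regions$end <= regions$start))
    stop("region with end <= start")
  df <- data.frame(chrom = regions$chrom, start = regions$start,
                   end = regions$end,
                   name = as.character(seq_len(nrow(regions))),
                   score = round(regions$mean_fold * 100))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d", df$chrom, as.integer(df$start),
                   as.integer(df$end), df$name, as.integer(df$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write genomic intervals as BED
#'
#' Used for centromere and subtelomere interval sets. Internal coordinates
#' are 0-based half-open, matching BED, so the round trip is exact.
#'
#' @param path BED file path.
#' @return a data.frame `chrom`, `start`, `end`.
#' @export
read_intervals_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED record with end <= start in ", path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' @rdname read_intervals_bed
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @export
write_intervals_bed <- function(intervals, path) {
  if (any(intervals$end <= intervals$start))
    stop("interval with end <= start")
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1, end = intervals$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read and write gene annotations as GFF3
#'
#' Genes are written as GFF3 `gene` features (1-based closed coordinates on
#' file, converted exactly from the internal 0-based half-open spans) with
#' `ID`, `expression` and `expression_class` attributes; the TSS/TES
#' orientation is reconstructed from the strand on read.
#'
#' @param path GFF3 file path.
#' @return for `read_genes`, a gene annotation data.frame as in
#'   `genome_model$genes`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  start0 <- GenomicRanges::start(gr) - 1   # GFF3 1-based closed -> 0-based half-open
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene without strand in ", path)
  plus <- strand == "+"
  data.frame(id = as.character(gr$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             tss = ifelse(plus, start0, end0),
             tes = ifelse(plus, end0, start0),
             expression_value = as.numeric(gr$expression),
             expression_class = as.character(gr$expression_class),
             stringsAsFactors = FALSE)
}

#' @rdname read_genes
#' @param genes gene annotation data.frame.
#' @export
write_genes <- function(genes, path) {
  gs <- pmin(genes$tss, genes$tes)
  ge <- pmax(genes$tss, genes$tes)
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = gs + 1, end = ge),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$id
  gr$expression <- sprintf("%.17g", genes$expression_value)
  gr$expression_class <- genes$expression_class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write qPCR replicate tables as TSV
#'
#' Dialect: columns `locus`, `antibody`, then one column per replicate
#' (`rep1`, `rep2`, ...), %IP units.
#'
#' @param path TSV file path.
#' @return for `read_qpcr`, a list of `qpcr_sample` objects.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  repcols <- grep("^rep", names(df), value = TRUE)
  if (length(repcols) == 0) stop("no replicate columns in ", path)
  lapply(seq_len(nrow(df)), function(i)
    qpcr_sample(df$locus[i], df$antibody[i],
                stats::na.omit(as.numeric(df[i, repcols]))))
}

#' @rdname read_qpcr
#' @param samples list of `qpcr_sample` objects.
#' @export
write_qpcr <- function(samples, path) {
  nrep <- max(vapply(samples, function(s) s$n, integer(1)))
  rows <- lapply(samples, function(s) {
    vals <- c(s$values, rep(NA, nrep - s$n))
    c(list(locus = s$locus, antibody = s$antibody),
      stats::setNames(as.list(vals), paste0("rep", seq_len(nrep))),
      list(mean = s$mean, sd = s$sd))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flat key-value configuration files
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path config file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: '", lines[i], "'")
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", format(config[[k]], scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

.read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  read_config(path)
}

.write_sidecar <- function(path, meta) write_config(meta, path)

.num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
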