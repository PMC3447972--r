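#' Analysis configuration
#'
#' Houses every numeric parameter of the pipeline with the published
#' defaults: 1 kb minimum region length, >2-fold threshold over the
#' genome-wide average, 100 kb centromere-proximity window, running average
#' over 100 probes, moving-average window of 100 genes with step 1, 99%
#' confidence intervals, and expression class boundaries at 8/10/12/14 a.u.
#'
#' @param min_region_length minimum enriched-region span (bp).
#' @param fold_threshold fold over genome-wide average a probe must exceed.
#' @param proximity_window distance from centromere edges defining
#'   "centromere-proximal" (bp).
#' @param smoothing_window running-average window (probes).
#' @param smooth logical; smooth the ratio track before domain calling
#'   (default `FALSE`: calling operates on raw probe ratios).
#' @param ma_window,ma_step moving-average window (genes) and step for the
#'   occupancy-versus-expression curve.
#' @param ci_level metagene confidence level.
#' @param class_boundaries expression class boundaries (a.u.), increasing.
#' @param bin_size hypergeometric population bin size (bp).
#' @param upstream,downstream,metagene_bin TSS window extents and bin (bp).
#' @param probe_spacing,noise_sd,global_fold,depletion_slope,n_spike
#'   simulation parameters passed through to [simulation_params()].
#' @param qpcr_cv coefficient of variation for simulated qPCR replicates.
#' @param seed integer seed driving every stage.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(min_region_length = 1000, fold_threshold = 2,
                            proximity_window = 100000,
                            smoothing_window = 100, smooth = FALSE,
                            ma_window = 100, ma_step = 1, ci_level = 0.99,
                            class_boundaries = c(8, 10, 12, 14),
                            bin_size = 1000,
                            upstream = 500, downstream = 2000,
                            metagene_bin = 20,
                            probe_spacing = 20, noise_sd = 0.25,
                            global_fold = 1, depletion_slope = 0,
                            n_spike = 2000, qpcr_cv = 0.05, seed = 1) {
  stopifnot(min_region_length > 0, fold_threshold > 0,
            proximity_window >= 0, smoothing_window >= 1, ma_window >= 1,
            ma_step >= 1, ci_level > 0, ci_level < 1,
            all(diff(class_boundaries) > 0), length(class_boundaries) == 4,
            bin_size > 0, qpcr_cv >= 0)
  structure(list(min_region_length = min_region_length,
                 fold_threshold = fold_threshold,
                 proximity_window = proximity_window,
                 smoothing_window = smoothing_window, smooth = smooth,
                 ma_window = ma_window, ma_step = ma_step,
                 ci_level = ci_level, class_boundaries = class_boundaries,
                 bin_size = bin_size, upstream = upstream,
                 downstream = downstream, metagene_bin = metagene_bin,
                 probe_spacing = probe_spacing, noise_sd = noise_sd,
                 global_fold = global_fold,
                 depletion_slope = depletion_slope, n_spike = n_spike,
                 qpcr_cv = qpcr_cv, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the end-to-end analysis on a simulated dataset
#'
#' Composes all stages: build the synthetic genome, simulate wild-type and
#' mutant arrays with spike-ins, spike-normalize, form the mutant/wild-type
#' ratio track, optionally smooth, call enriched regions, test their
#' centromere proximity, and compute the expression-stratified metagene
#' profile and the moving-average occupancy-versus-expression curve. When
#' `outdir` is given, all intermediate and final artifacts are written
#' there together with a machine-readable manifest and a stage log, so the
#' whole run is regenerable from the manifest alone. Identical config and
#' seed give identical result files.
#'
#' @param config an [analysis_config()].
#' @param outdir optional output directory (created if missing).
#' @param domains optional planted-domain data.frame (see
#'   [plant_domains()]); `NULL` plants nothing.
#' @param genome optional pre-built `genome_model`; by default one is built
#'   from `config$seed`.
#' @return a result bundle list: `genome`, `tracks`, `ratio`, `regions`,
#'   `proximity` (or NULL if no regions), `metagene`, `ma_curve`, `config`.
#' @export
run_pipeline <- function(config = analysis_config(), outdir = NULL,
                         domains = NULL, genome = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  if (is.null(genome)) {
    genome <- build_genome_model(genome_config(), seed = config$seed)
  }
  say("genome: ", nrow(genome$chromosomes), " chromosomes, ",
      nrow(genome$genes), " genes")

  params <- simulation_params(probe_spacing = config$probe_spacing,
                              noise_sd = config$noise_sd,
                              domains = domains,
                              global_fold = config$global_fold,
                              depletion_slope = config$depletion_slope,
                              n_spike = config$n_spike,
                              seed = config$seed)
  sim <- simulate_probe_tracks(genome, params)
  say("simulated ", sum(.chromosomal(sim$wt)), " chromosomal probes + ",
      nrow(sim$spikes), " spike-in probes per condition")

  wt_n <- scale_by_spike_ins(sim$wt, sim$spikes)
  mut_n <- scale_by_spike_ins(sim$mut, sim$spikes)
  global_fold_hat <- estimate_global_fold_change(sim$mut, sim$wt,
                                                 sim$spikes)
  say(sprintf("spike-normalized; global fold-change estimate %.3f",
              global_fold_hat))

  ratio <- ratio_track(mut_n, wt_n, scale = "linear")
  call_input <- if (isTRUE(config$smooth))
    running_average(ratio, config$smoothing_window) else ratio
  regions <- call_enriched_regions(call_input,
                                   min_length = config$min_region_length,
                                   fold_threshold = config$fold_threshold)
  say("called ", nrow(regions), " enriched regions")

  proximity <- NULL
  if (nrow(regions) > 0) {
    proximity <- test_proximity_enrichment(regions, genome,
                                           window = config$proximity_window,
                                           bin_size = config$bin_size)
    say(sprintf("proximity: %d/%d proximal, log10 p = %.1f",
                proximity$k_proximal, proximity$n_regions,
                proximity$log10_p))
  } else {
    say("no regions called; proximity test skipped")
  }

  ratio_log2 <- ratio_track(mut_n, wt_n, scale = "log2")
  profile <- NULL; ma <- NULL
  if (nrow(genome$genes) > 0) {
    mat <- tss_aligned_matrix(ratio_log2, genome$genes,
                              upstream = config$upstream,
                              downstream = config$downstream,
                              bin = config$metagene_bin)
    profile <- metagene_profile(mat, genome$genes$expression_class,
                                ci_level = config$ci_level)
    gb <- gene_body_means(ratio_log2, genome$genes)
    keep <- !is.na(gb)
    if (sum(keep) >= config$ma_window) {
      ma <- occupancy_vs_expression(gb[keep],
                                    genome$genes$expression_value[keep],
                                    window = config$ma_window,
                                    step = config$ma_step)
    } else {
      say("fewer genes than ma_window; occupancy curve skipped")
    }
    say("metagene: ", length(unique(profile$class)), " classes; ma-curve: ",
        if (is.null(ma)) 0 else nrow(ma), " points")
  } else {
    say("no genes; metagene stage skipped")
  }

  bundle <- list(genome = genome, tracks = sim, ratio = ratio,
                 regions = regions, proximity = proximity,
                 metagene = profile, ma_curve = ma,
                 global_fold_change = global_fold_hat, config = config)

  if (!is.null(outdir)) .write_bundle(bundle, outdir, log_lines)
  invisible(bundle)
}

.write_bundle <- function(bundle, outdir, log_lines) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_genes(bundle$genome$genes, p("genes.gff3"))
  write_intervals_bed(bundle$genome$centromeres, p("centromeres.bed"))
  if (nrow(bundle$genome$subtelomeres) > 0)
    write_intervals_bed(bundle$genome$subtelomeres, p("subtelomeres.bed"))
  write_track(bundle$tracks$wt, p("wt.bedgraph"))
  write_track(bundle$tracks$mut, p("mut.bedgraph"))
  write_track(bundle$ratio, p("ratio.bedgraph"))
  write_regions(bundle$regions, p("regions.bed"))
  if (!is.null(bundle$metagene))
    utils::write.table(bundle$metagene, p("metagene.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$ma_curve))
    utils::write.table(bundle$ma_curve, p("ma_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$proximity))
    jsonlite::write_json(unclass(bundle$proximity), p("proximity.json"),
                         auto_unbox = TRUE, digits = NA)
  cfg <- unclass(bundle$config)
  cfg$class_boundaries <- paste(cfg$class_boundaries, collapse = ",")
  write_config(unclass(cfg), p("config.txt"))
  manifest <- list(
    package = "cenmisloc",
    version = as.character(utils::packageVersion("cenmisloc")),
    seed = bundle$config$seed,
    parameters = cfg,
    counts = list(genes = nrow(bundle$genome$genes),
                  chromosomal_probes = sum(.chromosomal(bundle$tracks$wt)),
                  regions = nrow(bundle$regions)),
    global_fold_change = bundle$global_fold_change)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, p("log.txt"))
  invisible(outdir)
}
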