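# shared fixtures and independent brute-force oracles

# single-chromosome linear track from a value vector
toy_track <- function(values, spacing = 100, chrom = "chrT",
                      scale = "linear") {
  probe_track(data.frame(chrom = chrom,
                         pos = (seq_along(values) - 1) * spacing,
                         value = values),
              scale = scale, spacing = spacing)
}

# small genome for fast end-to-end runs: ~1.5 Mb over 3 chromosomes
small_genome <- function(seed = 1, n_genes = 300) {
  cfg <- genome_config(
    chrom_lengths = c(chr1 = 700000, chr2 = 500000, chr3 = 300000),
    centromere_spans = c(chr1 = 20000, chr2 = 25000, chr3 = 30000),
    subtelomere_length = 10000,
    n_genes = n_genes)
  build_genome_model(cfg, seed = seed)
}

# brute-force enriched-region oracle: enumerate all O(n^2) candidate
# intervals with marked endpoints and internal gaps <= max_gap, keep the
# maximal ones, then apply the length filter
brute_force_regions <- function(track, min_length = 1000,
                                fold_threshold = 2, max_gap = 0) {
  sp <- track_spacing(track)
  cutoff <- fold_threshold * genome_wide_average(track)
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    v <- track$value[sel]; pos <- track$pos[sel]
    marked <- v > cutoff
    n <- length(v)
    cand <- list()
    for (i in seq_len(n)) {
      if (!marked[i]) next
      for (j in i:n) {
        if (!marked[j]) next
        inner <- if (j > i) marked[i:j] else TRUE
        # longest internal run of unmarked probes
        gaps <- rle(inner)
        max_run <- if (any(!gaps$values)) max(gaps$lengths[!gaps$values]) else 0
        if (max_run <= max_gap) cand[[length(cand) + 1]] <- c(i, j)
      }
    }
    if (!length(cand)) next
    is_max <- vapply(seq_along(cand), function(a) {
      !any(vapply(seq_along(cand), function(b) {
        b != a && cand[[b]][1] <= cand[[a]][1] && cand[[b]][2] >= cand[[a]][2]
      }, logical(1)))
    }, logical(1))
    for (r in cand[is_max]) {
      start <- pos[r[1]]; end <- pos[r[2]] + sp
      if (end - start < min_length) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = start, end = end,
        n_probes = r[2] - r[1] + 1L,
        mean_fold = mean(v[r[1]:r[2]]))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_probes = integer(), mean_fold = numeric())
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
brute_force_hyper_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  marked <- seq_len(K)   # which population items are marked is arbitrary
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# per-gene minimum distance to any centromere by direct scan
brute_force_gene_distances <- function(genome) {
  g <- genome$genes
  vapply(seq_len(nrow(g)), function(i) {
    gs <- min(g$tss[i], g$tes[i]); ge <- max(g$tss[i], g$tes[i])
    cen <- genome$centromeres[genome$centromeres$chrom == g$chrom[i], ]
    if (nrow(cen) == 0) return(Inf)
    min(vapply(seq_len(nrow(cen)), function(j) {
      if (ge > cen$start[j] && gs < cen$end[j]) 0
      else if (ge <= cen$start[j]) cen$start[j] - ge
      else gs - cen$end[j]
    }, numeric(1)))
  }, numeric(1))
}
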