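test_that("proximal genome fraction reproduces the fixture arithmetic", {
  g <- build_genome_model(genome_config(n_genes = 0), seed = 1)
  expect_equal(proximal_genome_fraction(g, 0), 0)
  # six 100-kb flanks over 12.57 Mb = 4.8% (to one decimal in percent)
  frac <- proximal_genome_fraction(g, 100000)
  expect_equal(frac, 600000 / 12570000)
  expect_equal(round(100 * frac, 1), 4.8)
})

test_that("flanks are clipped at chromosome ends and exclude centromere bodies", {
  g <- small_genome(seed = 1, n_genes = 0)
  g$chromosomes <- data.frame(name = "chrA", length = 300000)
  g$centromeres <- data.frame(chrom = "chrA", start = 20000, end = 50000)
  g$subtelomeres <- g$subtelomeres[0, ]
  g$genes <- g$genes[0, ]
  # left flank clipped to [0, 20000) = 20 kb; right flank full 100 kb
  expect_equal(proximal_genome_fraction(g, 100000), 120000 / 300000)
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeometric_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeometric_tail(4, 4, 5, 10), 5 / 210)

  set.seed(11)
  for (i in 1:25) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeometric_tail(k, n, K, N),
                 brute_force_hyper_tail(k, n, K, N),
                 info = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
  }

  # monotone non-increasing in k
  tails <- vapply(0:6, function(k) hypergeometric_tail(k, 6, 30, 100),
                  numeric(1))
  expect_true(all(diff(tails) <= 0))

  expect_error(hypergeometric_tail(5, 4, 5, 10))
  expect_error(hypergeometric_tail(2, 4, 11, 10))
})

test_that("log-space tail stays finite and accurate deep in the tail", {
  lp <- hypergeometric_tail(96, 168, 600, 12355, log10_p = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, -50)
  p <- hypergeometric_tail(96, 168, 600, 12355)
  expect_equal(p, 10^lp, tolerance = 1e-6)
})

test_that("proximity test counts, proportions and saturation behave", {
  g <- build_genome_model(genome_config(n_genes = 0), seed = 1)
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(2700000, 100000, 2200000),
                        end = c(2702000, 102000, 2202000),
                        n_probes = 100, mean_fold = 6)
  res <- test_proximity_enrichment(regions, g)
  expect_equal(res$n_regions, 3)
  expect_equal(res$k_proximal, 2)  # chr1 mid-arm region is distal
  expect_equal(res$proportion * res$n_regions, res$k_proximal)

  # window spanning the whole genome: everything proximal, p = 1
  sat <- test_proximity_enrichment(regions, g, window = 6000000)
  expect_equal(sat$proportion, 1)
  expect_equal(sat$p_value, 1)

  expect_error(test_proximity_enrichment(regions[0, ], g), "no regions")
})

test_that("null placements give super-uniform p-values", {
  g <- build_genome_model(genome_config(n_genes = 0), seed = 1)
  # population of 1-kb bins outside centromeres, as the test itself uses
  res0 <- test_proximity_enrichment(
    data.frame(chrom = "chr1", start = 0, end = 1000), g)
  N <- res0$N; K <- res0$K
  n_draw <- 50

  # bin midpoints of the population, for placing regions uniformly
  bins <- do.call(rbind, lapply(seq_len(nrow(g$chromosomes)), function(i) {
    ch <- g$chromosomes$name[i]
    mids <- seq(500, g$chromosomes$length[i], by = 1000)
    cen <- g$centromeres[g$centromeres$chrom == ch, ]
    mids <- mids[!(mids >= cen$start & mids < cen$end)]
    data.frame(chrom = ch, mid = mids)
  }))
  expect_equal(nrow(bins), N)

  set.seed(99)
  # full-path check on a handful of placements: placing regions on sampled
  # bins and testing equals the closed-form tail at the same (K, N)
  for (i in 1:10) {
    pick <- bins[sample(N, n_draw), ]
    regions <- data.frame(chrom = pick$chrom, start = pick$mid - 500,
                          end = pick$mid + 500)
    res <- test_proximity_enrichment(regions, g)
    expect_equal(res$p_value,
                 hypergeometric_tail(res$k_proximal, n_draw, K, N))
  }

  # large replication via the equivalent bin draw (uniform w/o replacement)
  reps <- 2500
  pvals <- vapply(seq_len(reps), function(i) {
    k <- stats::rhyper(1, K, N - K, n_draw)
    hypergeometric_tail(k, n_draw, K, N)
  }, numeric(1))
  for (alpha in c(0.05, 0.01)) {
    mc_err <- 3 * sqrt(alpha * (1 - alpha) / reps)
    expect_lte(mean(pvals <= alpha), alpha + mc_err)
  }
})
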