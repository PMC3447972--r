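test_that("expression classification follows the published five-category scale", {
  expect_equal(classify_expression(14.5), "very_high")
  expect_equal(classify_expression(9.0), "low")
  expect_equal(classify_expression(c(5, 7.99, 8, 10, 11.9, 12, 14, 14.01)),
               c("very_low", "very_low", "low", "medium", "medium", "high",
                 "high", "very_high"))
  expect_error(classify_expression(NA_real_), "finite")
  expect_error(classify_expression(Inf), "finite")
})

test_that("TSS alignment is strand-aware and bin-exact", {
  # signal mirror-symmetric about position 5000 on a 100-bp grid
  n <- 100
  v <- stats::runif(n, 1, 4)
  v <- (v + rev(v)) / 2          # enforce the mirror symmetry
  track <- toy_track(v, spacing = 100, chrom = "chrM")
  genes <- data.frame(id = c("fwd", "rev"), chrom = "chrM",
                      strand = c("+", "-"),
                      tss = c(3000, 10000 - 3000),
                      tes = c(4500, 10000 - 4500),
                      expression_value = 9, expression_class = "low")
  mat <- tss_aligned_matrix(track, genes, upstream = 500, downstream = 1000,
                            bin = 100)
  expect_equal(unname(mat["fwd", ]), unname(mat["rev", ]))

  # constant track: all vectors constant
  cmat <- tss_aligned_matrix(toy_track(rep(2.5, n), chrom = "chrM"),
                             genes, upstream = 500, downstream = 1000,
                             bin = 100)
  expect_true(all(cmat == 2.5))

  # bin = spacing: the vector is the probe values verbatim
  g1 <- genes[1, ]
  m1 <- tss_aligned_matrix(track, g1, upstream = 200, downstream = 400,
                           bin = 100)
  expect_equal(unname(m1[1, ]), v[(31 - 2):(31 + 3)])

  # window exceeding the chromosome: gene skipped with a warning
  edge <- data.frame(id = "edge", chrom = "chrM", strand = "+", tss = 100,
                     tes = 900, expression_value = 9,
                     expression_class = "low")
  expect_warning(
    m2 <- tss_aligned_matrix(track, edge, upstream = 500, downstream = 1000,
                             bin = 100),
    "skipped")
  expect_true(all(is.na(m2)))
})

test_that("metagene profiles average classes with Student-t intervals", {
  pos <- c(-100, 0, 100)
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- pos
    attr(m, "positions") <- pos
    m
  }
  # all genes identical: mean is the vector, half-widths are zero
  m <- mk(rep(list(c(1, 2, 3)), 4))
  rownames(m) <- paste0("g", 1:4)
  suppressWarnings(prof <- metagene_profile(m, rep("medium", 4)))
  expect_equal(prof$mean, c(1, 2, 3))
  expect_equal(prof$ci_half_width, c(0, 0, 0))
  expect_equal(prof$n, c(4, 4, 4))

  # closed-form t interval for a two-gene class
  m2 <- mk(list(c(1, 4, 2), c(3, 8, 2)))
  suppressWarnings(prof2 <- metagene_profile(m2, rep("high", 2),
                                             ci_level = 0.99))
  a <- c(1, 4); b <- c(3, 8)
  expect_equal(prof2$mean[1:2], (a + b) / 2)
  expect_equal(prof2$ci_half_width[1],
               stats::qt(0.995, 1) * stats::sd(c(1, 3)) / sqrt(2))

  # gene order invariance
  m3 <- mk(list(c(1, 1, 1), c(5, 5, 5), c(2, 2, 2), c(4, 4, 4)))
  cls <- c("low", "high", "low", "high")
  suppressWarnings(p_fwd <- metagene_profile(m3, cls))
  perm <- c(3, 1, 4, 2)
  suppressWarnings(p_rev <- metagene_profile(m3[perm, ], cls[perm]))
  expect_equal(p_fwd, p_rev)

  # empty classes are excluded with a warning
  expect_warning(metagene_profile(m3, cls), "empty class")
})

test_that("99% intervals cover known class means at the nominal rate", {
  set.seed(5)
  n_genes <- 20; n_pos <- 10
  pos <- seq(0, by = 100, length.out = n_pos)
  classes <- expression_class_levels()
  covered <- 0L; cells <- 0L
  for (rep_i in 1:100) {
    mu <- matrix(stats::rnorm(5 * n_pos), nrow = 5,
                 dimnames = list(classes, pos))
    mats <- lapply(1:5, function(ci)
      matrix(stats::rnorm(n_genes * n_pos, mean = mu[ci, ], sd = 0.7),
             nrow = n_genes, byrow = TRUE))
    m <- do.call(rbind, mats)
    colnames(m) <- pos
    attr(m, "positions") <- pos
    prof <- metagene_profile(m, rep(classes, each = n_genes),
                             ci_level = 0.99)
    for (ci in 1:5) {
      sub <- prof[prof$class == classes[ci], ]
      hit <- abs(sub$mean - mu[ci, as.character(sub$position)]) <=
        sub$ci_half_width
      covered <- covered + sum(hit)
      cells <- cells + length(hit)
    }
  }
  expect_gte(cells, 5000)
  expect_gte(covered / cells, 0.97)
})

test_that("transcription-coupled depletion orders class means high to low", {
  g <- small_genome(seed = 6, n_genes = 400)
  p <- simulation_params(noise_sd = 0.25, depletion_slope = -0.1, seed = 16)
  sim <- simulate_probe_tracks(g, p)
  lr <- ratio_track(sim$mut, sim$wt, scale = "log2")
  gb <- gene_body_means(lr, g$genes)
  cls <- g$genes$expression_class
  means <- tapply(gb, cls, mean, na.rm = TRUE)
  ordered_cls <- c("very_high", "high", "medium", "low")
  present <- ordered_cls[ordered_cls %in% names(means)]
  expect_gte(length(present), 3)
  expect_true(all(diff(means[present]) > 0))
})

test_that("moving-average curves follow their defining arithmetic", {
  expect_equal(
    occupancy_vs_expression(rep(2, 150), stats::runif(150))$mean_occupancy,
    rep(2, 51))

  x <- stats::runif(100, 5, 15)
  one <- occupancy_vs_expression(seq_along(x), x, window = 100)
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_expression, mean(x))
  expect_equal(one$mean_occupancy, mean(seq_along(x)))

  # occupancy = -expression: the curve decreases strictly
  set.seed(3)
  e <- stats::runif(300, 5, 15)
  curve <- occupancy_vs_expression(-e, e, window = 100, step = 1)
  expect_equal(nrow(curve), 201)
  expect_true(all(diff(curve$mean_occupancy) < 0))
  expect_true(all(diff(curve$mean_expression) > 0))

  expect_error(occupancy_vs_expression(1:50, stats::runif(50), window = 100),
               "at least")
})
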