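make_spiked_track <- function(chrom_values, spike_obs, refs,
                              spacing = 100) {
  probes <- rbind(
    data.frame(chrom = "chr1", pos = (seq_along(chrom_values) - 1) * spacing,
               value = chrom_values),
    data.frame(chrom = "spikein", pos = (seq_along(spike_obs) - 1) * spacing,
               value = spike_obs))
  list(track = probe_track(probes, scale = "linear", spacing = spacing,
                           control_chroms = "spikein"),
       spikes = spike_in_set("spikein", (seq_along(refs) - 1) * spacing,
                             refs))
}

test_that("spike scaling is exact, idempotent, and consistent across arrays", {
  refs <- c(1, 2, 4)
  # track whose spike mean already equals the reference mean: unchanged
  x <- make_spiked_track(c(1, 5, 2), spike_obs = c(2, 3, 2), refs = refs)
  expect_equal(spike_scale_factor(x$track, x$spikes), 1)
  expect_equal(scale_by_spike_ins(x$track, x$spikes)$value, x$track$value)

  # track = 3 x reference-matching track: scaling inverts the factor
  y <- make_spiked_track(3 * c(1, 5, 2), spike_obs = 3 * c(2, 3, 2), refs)
  expect_equal(scale_by_spike_ins(y$track, y$spikes)$value, x$track$value)

  # idempotence
  once <- scale_by_spike_ins(y$track, y$spikes)
  twice <- scale_by_spike_ins(once, y$spikes)
  expect_equal(once$value, twice$value)

  # two arrays with identical spike observations get identical factors
  z <- make_spiked_track(c(9, 1, 1), spike_obs = 3 * c(2, 3, 2), refs)
  expect_equal(spike_scale_factor(y$track, y$spikes),
               spike_scale_factor(z$track, z$spikes))

  expect_error(spike_scale_factor(x$track, x$spikes[0, ]), "empty")
})

test_that("ratio tracks honor scale conventions and grid checks", {
  wt <- toy_track(c(1, 2, 4, 8))
  expect_equal(ratio_track(wt, wt)$value, rep(1, 4))
  expect_equal(ratio_track(wt, wt, scale = "log2")$value, rep(0, 4))

  mut <- toy_track(2 * c(1, 2, 4, 8))
  expect_equal(ratio_track(mut, wt)$value, rep(2, 4))
  expect_equal(ratio_track(mut, wt, scale = "log2")$value, rep(1, 4))

  # scale round trip probe-wise
  mut2 <- toy_track(c(3, 1, 5, 2))
  expect_equal(ratio_track(mut2, wt, scale = "log2")$value,
               log2(ratio_track(mut2, wt, scale = "linear")$value))

  short <- toy_track(c(1, 2, 3))
  expect_error(ratio_track(short, wt), "grid")
})

test_that("linear/log2 conversions are exact inverses", {
  x <- toy_track(c(0.5, 1, 2.7, 9))
  expect_equal(as_linear(as_log2(x))$value, x$value)
  expect_equal(track_scale(as_log2(x)), "log2")
})

test_that("running average matches a direct convolution oracle", {
  x <- toy_track(c(2, 7, 1, 9, 4))
  expect_equal(running_average(x, 1)$value, x$value)

  const <- toy_track(rep(3.3, 50))
  expect_equal(running_average(const, 7)$value, rep(3.3, 50))

  # unit impulse among zeros (log2 scale admits zeros), window 5
  imp <- toy_track(c(rep(0, 10), 1, rep(0, 10)), scale = "log2")
  sm <- running_average(imp, 5)
  expect_equal(sm$value[9:13], rep(0.2, 5))
  expect_equal(sm$value[c(1:8, 14:21)], rep(0, 16))

  # truncated edges: first value is the mean of the first 1 + half window
  v <- c(4, 8, 6, 2, 10, 12)
  sm2 <- running_average(toy_track(v, scale = "log2"), 3)
  expect_equal(sm2$value[1], mean(v[1:2]))
  expect_equal(sm2$value[6], mean(v[5:6]))
  expect_equal(sm2$value[3], mean(v[2:4]))

  # even windows are widened to the next odd; commutes with adding a constant
  expect_equal(running_average(toy_track(v, scale = "log2"), 4)$value,
               running_average(toy_track(v, scale = "log2"), 5)$value)
  shifted <- running_average(toy_track(v + 10, scale = "log2"), 3)
  expect_equal(shifted$value, sm2$value + 10)

  expect_error(running_average(toy_track(v), 9), "window")
})

test_that("global fold-change estimator is exact without noise and scale-invariant", {
  g <- small_genome(seed = 1, n_genes = 0)
  p <- simulation_params(noise_sd = 0, global_fold = 1.7, n_spike = 50,
                         spike_noise_sd = 0, seed = 3)
  sim <- simulate_probe_tracks(g, p)
  expect_equal(estimate_global_fold_change(sim$mut, sim$wt, sim$spikes), 1.7)
  expect_equal(estimate_global_fold_change(sim$wt, sim$wt, sim$spikes), 1)

  # invariance to pre-multiplying either array by a positive constant
  p2 <- simulation_params(noise_sd = 0.15, global_fold = 1.5, n_spike = 500,
                          seed = 4)
  sim2 <- simulate_probe_tracks(g, p2)
  base <- estimate_global_fold_change(sim2$mut, sim2$wt, sim2$spikes)
  mut_scaled <- probe_track(
    data.frame(chrom = sim2$mut$chrom, pos = sim2$mut$pos,
               value = 7.3 * sim2$mut$value),
    scale = "linear", spacing = track_spacing(sim2$mut),
    control_chroms = control_chroms(sim2$mut))
  expect_equal(estimate_global_fold_change(mut_scaled, sim2$wt, sim2$spikes),
               base)

  # array-level efficiency differences cancel through the spike controls
  p3 <- simulation_params(noise_sd = 0, global_fold = 2, n_spike = 50,
                          spike_noise_sd = 0, wt_array_scale = 0.6,
                          mut_array_scale = 2.4, seed = 5)
  sim3 <- simulate_probe_tracks(g, p3)
  expect_equal(estimate_global_fold_change(sim3$mut, sim3$wt, sim3$spikes), 2)
})
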