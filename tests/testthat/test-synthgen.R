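test_that("phantoms hit the target volume fraction deterministically", {
  ph <- make_phantom(c(32, 32, 32), target_bvtv = 0.2, seed = 4)
  expect_gte(ph$bvtv, 0.19)
  expect_lte(ph$bvtv, 0.21)
  ph2 <- make_phantom(c(32, 32, 32), target_bvtv = 0.2, seed = 4)
  expect_identical(ph$bone$data, ph2$bone$data)
  # single 6-connected component
  expect_equal(length(label_clusters(ph$bone)$volumes), 1L)
  # near-solid target: essentially the whole interior block
  solid <- make_phantom(c(16, 16, 16), target_bvtv = 0.97, seed = 1,
                        bone_margin = 3L)
  expect_gte(solid$bvtv, 0.96)
})

test_that("signal fields have the advertised shape properties", {
  ph <- make_phantom(c(16, 16, 16), target_bvtv = 0.3, seed = 2)
  ramp <- make_signal_field(ph, "ramp", sed_min = 0, sed_max = 0.02)
  g <- sed_gradient_norm(scalar_volume(ramp$data, ramp$voxel_size))
  slope <- 0.02 / ((16 - 1) * 10.5)
  interior <- g$data[2:15, 2:15, 2:15]
  expect_equal(as.vector(interior), rep(slope, length(interior)),
               tolerance = 1e-9)

  rad <- make_signal_field(ph, "radial", sed_min = 0.001, sed_max = 0.02)
  mid <- dim(rad$data)[1] %/% 2
  center_val <- rad$data[mid, 8, 8]
  edge_val <- rad$data[mid, 8, 16]
  expect_lt(center_val, edge_val)     # monotone in radius

  fe <- make_signal_field(list(bone = bv(array(1L, c(6, 6, 6)))), "fe")
  expect_equal(as.vector(fe$data), rep(0.74, 6^3), tolerance = 1e-6)
})

test_that("a zero-velocity rule leaves the image untouched", {
  truth0 <- mechanostat_truth("piecewise",
    c(RSL = 0, RVM = 1, RT = 0, FT = 0, FVM = 1, FSL = 0))
  ph <- make_phantom(c(24, 24, 24), target_bvtv = 0.25, seed = 3)
  field <- effective_strain_field(
    scalar_volume(array(1e-4, c(24, 24, 24)), 10.5), 14800)
  ev <- evolve_mechanostat(ph$bone, field, truth0, mask = ph$mask, seed = 1)
  expect_identical(ev$followup$data, ph$bone$data)
  expect_true(all(ev$truth_table$event == "quiescence"))
})

test_that("uniform growth thickens a flat slab by the commanded layers", {
  d <- c(12, 9, 9)
  base <- array(0L, d); base[2:4, 2:8, 2:8] <- 1L
  mask <- array(1L, d)
  # saturated formation branch: RmV = FSL everywhere, 2 voxels in 7 days
  fsl <- 2 * 10.5 / 7
  truth <- mechanostat_truth("piecewise",
    c(RSL = 0, RVM = 1, RT = 0, FT = 0, FVM = 10, FSL = fsl))
  field <- effective_strain_field(
    scalar_volume(array(0.5, d), 10.5), 14800)
  ev <- evolve_mechanostat(bv(base), field, truth, mask = bv(mask),
                           seed = 2)
  top <- ev$truth_table[ev$truth_table$z == 4, ]
  expect_true(all(top$applied_vox == 2))
  expect_true(all(ev$followup$data[5:6, 2:8, 2:8] == 1L))
  # pipeline recovers exactly 2 voxels on the grown surface
  tb <- build_surface_table(bv(base), ev$followup, bv(mask))
  grown <- tb[tb$z == 4 & tb$event == "formation", ]
  expect_equal(mean(grown$distance_vox), 2, tolerance = 0.15)
  expect_equal(sum(tb$distance_vox),
               sum(ev$followup$data) - sum(base), tolerance = 1e-9)
})

test_that("advection bookkeeping matches the realized voxel changes", {
  truth <- default_truth()
  for (seed in c(1, 2, 3)) {
    s <- synth_sample(seed, truth, shape = c(32L, 32L, 32L), sigma = 1.5)
    net <- sum(s$followup$data) - sum(s$baseline$data)
    expect_equal(net, sum(s$truth_table$applied_vox))
    # probabilistic rounding is unbiased given the target displacements
    tt <- s$truth_table
    expect_lt(abs(mean(tt$rounded_vox) - mean(tt$target_vox)), 0.03)
    # determinism
    s2 <- synth_sample(seed, truth, shape = c(32L, 32L, 32L), sigma = 1.5)
    expect_identical(s2$followup$data, s$followup$data)
  }
})

test_that("the pipeline reproduces a noise-free truth curve closely", {
  truth <- default_truth(noise = 0)
  tabs <- list()
  for (seed in 1:3) {
    s <- synth_sample(seed, truth)
    tb <- build_surface_table(s$baseline, s$followup, s$mask)
    tabs[[seed]] <- sample_surface_signal(tb, s$field, s$baseline)
  }
  g <- group_average_curve(tabs, voxel_size = 10.5, interval_days = 7)
  ok <- !is.na(g$rmv)
  resid <- g$rmv[ok] - truth$rmv(g$signal[ok])
  # within half a voxel layer of velocity wherever the signal is populated
  half_layer <- 0.5 * 10.5 / 7
  expect_lt(stats::quantile(abs(resid), 0.95), half_layer)
})
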