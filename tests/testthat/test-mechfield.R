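test_that("effective strain inverts the SED definition voxel-wise", {
  sed <- sv(array(0.74, c(3, 3, 3)))
  es <- effective_strain_field(sed, 14800)
  expect_equal(unique(as.vector(es$data)), 10000)   # U = E eps^2 / 2 at 1%
  expect_equal(es$sampling_side, "bone")

  zero <- effective_strain_field(sv(array(0, c(3, 3, 3))), 14800)
  expect_true(all(zero$data == 0))

  set.seed(2)
  U <- array(runif(64, 0, 0.5), c(4, 4, 4))
  E <- array(runif(64, 5000, 20000), c(4, 4, 4))
  es2 <- effective_strain_field(sv(U), sv(E))
  expect_equal(es2$data, sqrt(2 * U / E) * 1e6, tolerance = 1e-12)
  expect_error(effective_strain_field(sv(array(1, c(3, 3, 3))), 0), "modulus")
})

test_that("SED gradient norm matches finite differences and their invariances", {
  # linear field: constant gradient at every voxel incl. one-sided borders
  d <- c(5, 4, 4); h <- 10
  z <- array(rep((seq_len(d[1]) - 1) * h, times = prod(d[2:3])), dim = d)
  g <- sed_gradient_norm(sv(0.002 * z, vs = h))
  expect_equal(as.vector(g$data), rep(0.002, prod(d)), tolerance = 1e-12)
  expect_equal(g$sampling_side, "marrow")

  expect_true(all(sed_gradient_norm(sv(array(3, c(3, 3, 3))))$data == 0))

  set.seed(9)
  U <- array(runif(5 * 6 * 7), c(5, 6, 7))
  got <- sed_gradient_norm(sv(U, vs = 2))
  # index-wise oracle
  num_grad <- function(arr, axis, h) {
    d <- dim(arr); g <- array(0, d)
    idx <- function(i) switch(axis, arr[i, , , drop = FALSE],
                              arr[, i, , drop = FALSE],
                              arr[, , i, drop = FALSE])
    n <- d[axis]
    for (i in seq_len(n)) {
      lo <- max(i - 1, 1); hi <- min(i + 1, n)
      val <- (idx(hi) - idx(lo)) / ((hi - lo) * h)
      if (axis == 1) g[i, , ] <- val else if (axis == 2) g[, i, ] <- val
      else g[, , i] <- val
    }
    g
  }
  ref <- sqrt(num_grad(U, 1, 2)^2 + num_grad(U, 2, 2)^2 +
                num_grad(U, 3, 2)^2)
  expect_equal(got$data, ref, tolerance = 1e-12)
  # invariant to adding a constant
  shifted <- sed_gradient_norm(sv(U + 5, vs = 2))
  expect_equal(shifted$data, got$data, tolerance = 1e-12)
  expect_error(sed_gradient_norm(sv(array(1, c(2, 3, 3)))), "degenerate")
})

test_that("density-to-modulus conversion applies the linear map with a floor", {
  map <- material_map("heterogeneous", density_slope = 10,
                      density_intercept = -500)
  dens <- sv(array(c(0, 50, 100, 800), c(4, 1, 1)))
  E <- density_to_modulus(dens, map)
  expect_equal(as.vector(E$data), c(2, 2, 500, 7500))  # floor at 2 MPa
  ramp <- sv(array(seq(100, 800, length.out = 8), c(2, 2, 2)))
  E2 <- density_to_modulus(ramp, map)
  expect_equal(as.vector(E2$data), pmax(10 * as.vector(ramp$data) - 500, 2))
  expect_error(material_map("heterogeneous"), "density_slope")
  expect_error(density_to_modulus(dens, material_map()), "heterogeneous")
})

test_that("force rescaling is linear in strain, quadratic in energy, composable", {
  U <- sv(array(runif(27), c(3, 3, 3)))
  sed <- signal_field(U, "sed")
  strain <- effective_strain_field(U, 10000)
  expect_equal(rescale_to_force(sed, 10, 8)$data, U$data * 0.64)
  expect_equal(rescale_to_force(strain, 10, 8)$data, strain$data * 0.8)
  expect_equal(rescale_to_force(sed, 5, 5)$data, sed$data)
  ab <- rescale_to_force(rescale_to_force(sed, 4, 6), 6, 9)
  expect_equal(ab$data, rescale_to_force(sed, 4, 9)$data, tolerance = 1e-12)
  expect_error(rescale_to_force(sed, -1, 2), "positive")
})

test_that("signals are sampled on the side dictated by their kind", {
  # 3-layer phantom: bone z=1:2, marrow z=3:5
  d <- c(5, 4, 4)
  bone <- array(0L, d); bone[1:2, , ] <- 1L
  U <- array(rep(1:5, times = prod(d[2:3])), dim = d)  # value = z index
  tbl <- tibble::tibble(z = 2L, y = 2L, x = 2L,
                        event = factor("quiescence",
                                       levels = c("formation", "quiescence",
                                                  "resorption")),
                        distance_vox = 0, cluster_id = NA_integer_,
                        signal = NA_real_)
  sed <- signal_field(sv(U), "sed")
  got_bone <- sample_surface_signal(tbl, sed, bv(bone))
  expect_equal(got_bone$signal, 2)        # the bone voxel's own value

  grad <- structure(sed, class = class(sed)); grad$kind <- "grad_sed_norm"
  grad$sampling_side <- "marrow"
  got_marrow <- sample_surface_signal(tbl, grad, bv(bone))
  expect_equal(got_marrow$signal, 3)      # one step into marrow (z = 3)

  # constant field: both sides read the same value
  const <- signal_field(sv(array(7, d)), "sed")
  constg <- structure(const, class = class(const))
  constg$kind <- "grad_sed_norm"; constg$sampling_side <- "marrow"
  expect_equal(sample_surface_signal(tbl, const, bv(bone))$signal, 7)
  expect_equal(sample_surface_signal(tbl, constg, bv(bone))$signal, 7)
})
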