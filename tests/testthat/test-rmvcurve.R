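mk_table <- function(event, distance, signal) {
  tibble::tibble(
    z = 1L, y = 1L, x = 1L,
    event = factor(event, levels = c("formation", "quiescence",
                                     "resorption")),
    distance_vox = distance, cluster_id = NA_integer_, signal = signal)
}

test_that("velocity conversion and the quiescent-zero convention", {
  allq <- mk_table(rep("quiescence", 20), rep(0, 20), runif(20, 0, 100))
  cv <- compute_rmv_curve(allq, voxel_size = 10.5, interval_days = 7)
  expect_true(all(cv$rmv[!is.na(cv$rmv)] == 0))

  # one formation voxel: 2 vox * 10.5 um / 7 d = 3 um/day
  one <- mk_table("formation", 2, 50)
  cv1 <- compute_rmv_curve(one, voxel_size = 10.5, interval_days = 7,
                           distance_binning = "raw")
  expect_equal(cv1$rmv[!is.na(cv1$rmv)], 3)
  # the 1%-of-max distance histogram quantizes by at most half a bin
  cv1b <- compute_rmv_curve(one, voxel_size = 10.5, interval_days = 7)
  expect_equal(cv1b$rmv[!is.na(cv1b$rmv)], 3, tolerance = 0.0051)
  # adding a quiescent voxel to the same bin halves the weighted mean
  two <- dplyr::bind_rows(one, mk_table("quiescence", 0, 50))
  cv2 <- compute_rmv_curve(two, voxel_size = 10.5, interval_days = 7,
                           distance_binning = "raw")
  expect_equal(cv2$rmv[!is.na(cv2$rmv)], 1.5)
  expect_error(compute_rmv_curve(one, voxel_size = 10.5,
                                 interval_days = 0), "interval")
})

test_that("raw-binned curves satisfy the weighted-mean volume identity", {
  set.seed(41)
  n <- 500
  tab <- mk_table(sample(c("formation", "quiescence", "resorption"), n,
                         replace = TRUE), 0, runif(n, 0, 600))
  tab$distance_vox <- ifelse(tab$event == "formation", runif(n, 0.5, 3),
                             ifelse(tab$event == "resorption",
                                    -runif(n, 0.5, 2), 0))
  cv <- compute_rmv_curve(tab, voxel_size = 10.5, interval_days = 7,
                          distance_binning = "raw")
  ok <- !is.na(cv$rmv)
  lhs <- sum(cv$rmv[ok] * cv$counts[ok]) * 7 / 10.5
  expect_equal(lhs, sum(tab$distance_vox), tolerance = 1e-9)
  # distance-axis snapping changes each value by at most half a bin
  cvb <- compute_rmv_curve(tab, voxel_size = 10.5, interval_days = 7)
  half_bin <- max(abs(tab$distance_vox)) / 100 / 2 * 10.5 / 7
  expect_true(all(abs(cvb$rmv[ok] - cv$rmv[ok]) <= half_bin + 1e-12))
})

test_that("group averaging masks bins seen in fewer than three samples", {
  mk_sample <- function(lo, hi) {
    n <- 200
    mk_table(rep("formation", n), runif(n, 1, 2), runif(n, lo, hi))
  }
  set.seed(4)
  tabs <- list(mk_sample(0, 600), mk_sample(0, 600), mk_sample(0, 600),
               mk_sample(0, 300), mk_sample(0, 300))
  g <- group_average_curve(tabs, voxel_size = 10.5, interval_days = 7)
  expect_true(all(g$n_samples[!is.na(g$rmv)] >= 3))
  # three identical samples average to the per-sample curve
  one <- mk_sample(0, 600)
  g3 <- group_average_curve(list(one, one, one), voxel_size = 10.5,
                            interval_days = 7)
  single <- compute_rmv_curve(one, voxel_size = 10.5, interval_days = 7,
                              cap = attr(g3, "cap"))
  expect_equal(g3$rmv, single$rmv, tolerance = 1e-12)
  # per-bin arithmetic-mean oracle
  curves <- lapply(tabs, compute_rmv_curve, voxel_size = 10.5,
                   interval_days = 7, cap = attr(g, "cap"))
  for (b in which(!is.na(g$rmv))) {
    vals <- vapply(curves, function(cv) cv$rmv[b], 0)
    expect_equal(g$rmv[b], mean(vals, na.rm = TRUE), tolerance = 1e-12)
  }
  expect_error(group_average_curve(tabs[1:2], 10.5, 7), "at least 3")
})

test_that("piecewise fits recover generating parameters on exact curves", {
  pars <- c(RSL = -2, RVM = 0.04, RT = 150, FT = 300, FVM = 0.02, FSL = 2)
  cv <- curve_from_fn(function(ms) piecewise_rmv(ms, pars["RSL"],
                                                 pars["RVM"], pars["RT"],
                                                 pars["FT"], pars["FVM"],
                                                 pars["FSL"]))
  fit <- fit_piecewise(cv)
  expect_true(all(abs(fit$parameters - pars) / abs(pars) < 0.01))
  expect_lte(fit$rmse, 1e-6)
  # continuity of the assembled function at the four breakpoints
  p <- fit$parameters
  expect_equal(predict_mechanostat(fit, p["RT"]), 0, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(predict_mechanostat(fit, p["FT"]), 0, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(predict_mechanostat(fit, p["RT"] + p["RSL"] / p["RVM"]),
               unname(p["RSL"]), ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(predict_mechanostat(fit, p["FT"] + p["FSL"] / p["FVM"]),
               unname(p["FSL"]), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("hyperbola fits recover parameters and report the zero crossing", {
  cv <- curve_from_fn(function(ms) hyperbola_rmv(ms, 2, 800, 250))
  fit <- fit_hyperbola(cv)
  expect_equal(unname(fit$parameters[c("FSL", "RmVM", "RmT")]),
               c(2, 800, 250), tolerance = 0.01)
  expect_lte(fit$rmse, 1e-6)
  # closed-form zero crossing RmVM/FSL - RmT, checked on a physiological
  # sham-loading parameter set
  sham <- c(FSL = 0.274, RmVM = 236, RmT = 482)
  cv2 <- curve_from_fn(function(ms) hyperbola_rmv(ms, sham["FSL"],
                                                  sham["RmVM"],
                                                  sham["RmT"]),
                       ms = seq(10, 1280, length.out = 100))
  fit2 <- fit_hyperbola(cv2)
  expect_equal(unname(fit2$parameters["zero_crossing"]),
               236 / 0.274 - 482, tolerance = 0.01)
  expect_equal(hyperbola_rmv(236 / 0.274 - 482, 0.274, 236, 482), 0,
               tolerance = 1e-12)
  # RSL is the fitted function at the minimum observed signal
  expect_equal(unname(fit2$parameters["RSL"]),
               hyperbola_rmv(10, fit2$parameters["FSL"],
                             fit2$parameters["RmVM"],
                             fit2$parameters["RmT"]),
               ignore_attr = TRUE, tolerance = 1e-9)

  # degenerate flat curve: RmVM ~ 0 reproduces a constant
  cv3 <- curve_from_fn(function(ms) rep(1, length(ms)))
  fit3 <- fit_hyperbola(cv3)
  expect_lte(fit3$rmse, 1e-8)
})

test_that("both fits are scale-equivariant in the velocity axis", {
  fn <- function(ms) piecewise_rmv(ms, -2, 0.04, 150, 300, 0.02, 2)
  cv <- curve_from_fn(fn)
  cv3 <- curve_from_fn(function(ms) 3 * fn(ms))
  f1 <- fit_piecewise(cv); f3 <- fit_piecewise(cv3)
  expect_equal(f3$parameters[c("RSL", "FSL", "RVM", "FVM")],
               3 * f1$parameters[c("RSL", "FSL", "RVM", "FVM")],
               tolerance = 1e-3)
  expect_equal(f3$parameters[c("RT", "FT")], f1$parameters[c("RT", "FT")],
               tolerance = 1e-3)

  hn <- function(ms) hyperbola_rmv(ms, 1.5, 600, 200)
  h1 <- fit_hyperbola(curve_from_fn(hn))
  h3 <- fit_hyperbola(curve_from_fn(function(ms) 3 * hn(ms)))
  expect_equal(unname(h3$parameters[c("FSL", "RmVM")]),
               unname(3 * h1$parameters[c("FSL", "RmVM")]),
               tolerance = 1e-3)
  expect_equal(unname(h3$parameters["RmT"]), unname(h1$parameters["RmT"]),
               tolerance = 1e-2)
})

test_that("fits beat the constant-mean model on mechanostat-shaped data", {
  set.seed(12)
  fn <- function(ms) piecewise_rmv(ms, -1.5, 0.03, 180, 320, 0.015, 1.8)
  ms <- seq(6, 594, length.out = 100)
  y <- fn(ms) + rnorm(100, sd = 0.1)
  cv <- mechanostat:::new_rmv_curve(
    tibble::tibble(bin = 1:100, signal = ms, rmv = y,
                   counts = rep(20L, 100), n_samples = 3L),
    cap = 600, voxel_size = 10.5, interval_days = 7)
  base_rmse <- sqrt(mean((y - mean(y))^2))
  expect_lt(fit_piecewise(cv)$rmse, base_rmse)
  expect_lt(fit_hyperbola(cv)$rmse, base_rmse)
})

test_that("an all-nonnegative curve flags the resorption branch", {
  cv <- curve_from_fn(function(ms) pmax(0.01 * (ms - 300), 0))
  fit <- fit_piecewise(cv)
  expect_true("resorption_branch_unidentifiable" %in% fit$flags)
  expect_identical(glance(fit)$flags, "resorption_branch_unidentifiable")
  expect_equal(nrow(tidy(fit)), 6L)
})
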