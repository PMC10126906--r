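test_that("remodeling classification agrees with boolean set algebra", {
  pair <- slab_pair()
  rem <- classify_remodeling(pair$baseline, pair$baseline, pair$mask)
  expect_equal(sum(rem$formed$data), 0L)
  expect_equal(sum(rem$resorbed$data), 0L)

  rem2 <- classify_remodeling(pair$baseline, pair$followup, pair$mask)
  expect_equal(sum(rem2$formed$data), 25L)

  set.seed(21)
  a <- array(rbinom(512, 1, 0.4), c(8, 8, 8))
  b <- array(rbinom(512, 1, 0.4), c(8, 8, 8))
  m <- array(rbinom(512, 1, 0.9), c(8, 8, 8))
  rem3 <- classify_remodeling(bv(a), bv(b), bv(m))
  expect_identical(rem3$formed$data, (b & !a & m) * 1L)
  expect_identical(rem3$resorbed$data, (a & !b & m) * 1L)
  expect_identical(rem3$quiescent_bone$data, (a & b & m) * 1L)
  # the three sets partition: formed+quiescent = follow-up bone in mask
  expect_identical(rem3$formed$data + rem3$quiescent_bone$data, (b & m) * 1L)
  expect_error(classify_remodeling(bv(a), bv(array(0L, c(4, 4, 4))), bv(m)),
               "mismatch")
  expect_error(classify_remodeling(bv(a), bv(b), bv(array(0L, c(8, 8, 8)))),
               "empty")
})

test_that("surface voxels are those with a background face neighbor", {
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_identical(surface_mask(bv(single))$data, single)

  cube <- array(0L, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  s <- surface_mask(bv(cube))
  expect_equal(sum(s$data), 26L)          # 3^3 minus the single interior voxel
  expect_equal(s$data[3, 3, 3], 0L)

  expect_equal(sum(surface_mask(bv(array(0L, c(4, 4, 4))))$data), 0L)
  # out-of-bounds counts as background: a full block is all surface at faces
  full <- surface_mask(bv(array(1L, c(3, 3, 3))))
  expect_equal(sum(full$data), 26L)
})

test_that("taxicab distance transform equals the exhaustive L1 oracle", {
  # interior line of a full-width slab realizes the 1D [0,1,1,1,0] case
  slab <- array(0L, c(7, 7, 5)); slab[, , 2:4] <- 1L
  dt <- taxicab_dt(bv(slab))
  expect_equal(dt$data[4, 4, ], c(0, 1, 2, 1, 0))

  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_equal(taxicab_dt(bv(single))$data[2, 2, 2], 1)

  set.seed(5)
  for (p in c(0.3, 0.6, 0.9)) {
    arr <- array(rbinom(1000, 1, p), c(10, 10, 10))
    expect_equal(taxicab_dt(bv(arr))$data, oracle_l1_dt(arr),
                 label = sprintf("fill %.1f", p))
  }
})

test_that("cluster labels partition the foreground with 6-connectivity", {
  a <- array(0L, c(5, 5, 5))
  a[2, 2, 2] <- 1L
  a[2, 2, 3] <- 1L        # face neighbor: same cluster
  a[4, 4, 4] <- 1L        # far away: second cluster
  a[3, 3, 3] <- 1L        # diagonal to others: own cluster under 6-conn
  cl <- label_clusters(bv(a))
  expect_equal(length(cl$volumes), 3L)
  expect_equal(sum(cl$volumes), 4L)
  expect_equal(sort(unname(cl$volumes)), c(1L, 1L, 2L))
  expect_true(all(cl$labels[a == 1L] > 0L))
  expect_true(all(cl$labels[a == 0L] == 0L))
})

test_that("event surfaces follow the dilation-overlap rule with precedence", {
  d <- c(7, 7, 7)
  base0 <- array(0L, d); base0[2:4, 2:6, 2:6] <- 1L
  grow1 <- base0; grow1[5, 4, 4] <- 1L        # one voxel added atop the slab
  rem <- classify_remodeling(bv(base0), bv(grow1), bv(array(1L, d)))
  surf <- surface_mask(bv(base0))
  tbl <- label_event_surfaces(surf, rem)
  # the slab surface voxel directly beneath the added voxel is formation
  expect_equal(as.character(tbl$event[tbl$z == 4 & tbl$y == 4 & tbl$x == 4]),
               "formation")
  # a surface voxel with neither event nearby stays quiescent
  expect_equal(as.character(tbl$event[tbl$z == 2 & tbl$y == 3 & tbl$x == 3]),
               "quiescence")

  # removing a surface voxel labels it resorption
  base <- array(0L, d); base[2:4, 2:6, 2:6] <- 1L
  foll <- base; foll[4, 4, 4] <- 0L
  rem2 <- classify_remodeling(bv(base), bv(foll), bv(array(1L, d)))
  tbl2 <- label_event_surfaces(surface_mask(bv(base)), rem2)
  expect_equal(as.character(tbl2$event[tbl2$z == 4 & tbl2$y == 4 &
                                         tbl2$x == 4]), "resorption")

  # collision: voxel resorbed AND adjacent to formation -> resorption + warning
  foll3 <- base; foll3[4, 4, 4] <- 0L; foll3[5, 4, 4] <- 1L
  rem3 <- classify_remodeling(bv(base), bv(foll3), bv(array(1L, d)))
  expect_warning(
    tbl3 <- label_event_surfaces(surface_mask(bv(base)), rem3),
    "resorption")
  expect_equal(as.character(tbl3$event[tbl3$z == 4 & tbl3$y == 4 &
                                         tbl3$x == 4]), "resorption")
})

test_that("gray dilation projects the added layer's distance, not the old surface's", {
  pair <- slab_pair()                     # full 1-voxel layer added
  tbl <- build_surface_table(pair$baseline, pair$followup, pair$mask)
  form <- tbl[tbl$event == "formation", ]
  expect_equal(nrow(form), 25L)
  # each capped surface voxel reads 1 from the added layer (its own
  # follow-up DT value would be 2)
  expect_true(all(form$distance_vox == 1))

  # two added layers: outer-layer DT values projected, volume-scaled
  d <- c(8, 7, 7)
  base <- array(0L, d); base[2:4, 2:6, 2:6] <- 1L
  foll <- base; foll[5:6, 2:6, 2:6] <- 1L
  tb2 <- build_surface_table(bv(base), bv(foll), bv(array(1L, d)))
  f2 <- tb2[tb2$event == "formation", ]
  expect_equal(sum(f2$distance_vox), 50)  # cluster volume conserved
  center <- f2[f2$y %in% 3:5 & f2$x %in% 3:5, ]
  expect_true(all(center$distance_vox >= 2))  # interior columns carry depth 2
})

test_that("cluster-volume scaling conserves volume exactly", {
  s1 <- scale_cluster_distances(c(1, 1, 2), c(1L, 1L, 1L), c("1" = 4L))
  expect_equal(s1$scaled, c(1, 1, 2))     # already consistent, factor 1
  s2 <- scale_cluster_distances(c(2, 2), c(1L, 1L), c("1" = 2L))
  expect_equal(s2$scaled, c(1, 1))        # factor forced to 0.5
  s3 <- scale_cluster_distances(c(1, 3), c(1L, 2L), c("1" = 5L, "2" = 6L,
                                                      "3" = 9L))
  expect_equal(s3$scaled, c(5, 6))
  expect_equal(s3$orphans, 3L)            # cluster 3 unattributed
  expect_error(scale_cluster_distances(c(0), c(1L), c("1" = 2L)), "zero")
})

test_that("surface tables conserve per-cluster and net volumes on random pairs", {
  truth <- default_truth()
  for (seed in 1:8) {
    s <- synth_sample(seed, truth, shape = c(28L, 28L, 28L), sigma = 1.5)
    tbl <- build_surface_table(s$baseline, s$followup, s$mask)
    qc <- attr(tbl, "qc")
    # per-cluster sums equal cluster voxel counts
    form <- tbl[tbl$event == "formation", ]
    if (nrow(form) > 0) {
      sums <- tapply(form$distance_vox, form$cluster_id, sum)
      expect_true(all(abs(sums - round(sums)) < 1e-9 * pmax(sums, 1)))
    }
    # signed sum equals net voxel change (orphan clusters accounted)
    net <- sum(s$followup$data * s$mask$data) -
      sum(s$baseline$data * s$mask$data)
    expect_equal(sum(tbl$distance_vox) + qc$orphan_formation_volume -
                   qc$orphan_resorption_volume, net, tolerance = 1e-9)
    # every baseline surface voxel appears exactly once
    surf <- surface_mask(bv(s$baseline$data * s$mask$data))
    expect_equal(nrow(tbl), sum(surf$data))
    expect_false(any(duplicated(tbl[, c("z", "y", "x")])))
  }
})

test_that("an identical pair yields an all-quiescent table", {
  pair <- slab_pair()
  tbl <- build_surface_table(pair$baseline, pair$baseline, pair$mask)
  expect_true(all(tbl$event == "quiescence"))
  expect_true(all(tbl$distance_vox == 0))
})
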