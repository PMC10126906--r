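#' Synthetic trabecular phantoms with known mechanostat ground truth
#'
#' The generator produces trabecular-like binary microstructures (smoothed
#' seeded noise, thresholded to a target bone volume fraction), a smooth
#' positive SED-like field, and a follow-up image obtained by advecting the
#' bone surface under a known mechanostat rule: per surface voxel the target
#' displacement is `RmV(signal) * interval_days / voxel_size` voxels plus
#' Gaussian velocity noise, realized as whole voxel layers along the local
#' surface normal (approximated by a marrow face-neighbor direction) with
#' probabilistic rounding so the expected added volume matches the target
#' exactly. Every stage of the analysis pipeline can thus be validated
#' against exact per-voxel ground truth.
#'
#' @name synthgen
NULL

#' Mechanostat ground-truth rule
#'
#' @param kind `"piecewise"` or `"hyperbola"`.
#' @param parameters named vector: for piecewise `RSL, RVM, RT, FT, FVM,
#'   FSL`; for hyperbola `FSL, RmVM, RmT` (units as in
#'   [mechanostat_functions]).
#' @param interval_days days between baseline and follow-up.
#' @param voxel_size voxel edge (um).
#' @param noise standard deviation of per-voxel velocity noise (um/day).
#' @return a `mechanostat_truth` object with an `rmv(ms)` evaluator.
#' @export
mechanostat_truth <- function(kind = c("piecewise", "hyperbola"),
                              parameters, interval_days = 7,
                              voxel_size = 10.5, noise = 0) {
  kind <- match.arg(kind)
  p <- parameters
  if (kind == "piecewise") {
    needed <- c("RSL", "RVM", "RT", "FT", "FVM", "FSL")
    stopifnot(all(needed %in% names(p)))
    if (p["RSL"] > 0 || p["FSL"] < 0 || p["RVM"] <= 0 || p["FVM"] <= 0 ||
        p["RT"] > p["FT"]) {
      stop("invalid piecewise mechanostat parameters", call. = FALSE)
    }
    fn <- function(ms) piecewise_rmv(ms, p["RSL"], p["RVM"], p["RT"],
                                     p["FT"], p["FVM"], p["FSL"])
  } else {
    needed <- c("FSL", "RmVM", "RmT")
    stopifnot(all(needed %in% names(p)))
    if (p["RmVM"] < 0) stop("RmVM must be >= 0", call. = FALSE)
    fn <- function(ms) {
      if (any(p["RmT"] + ms <= 0)) {
        stop("hyperbola pole inside the signal range", call. = FALSE)
      }
      hyperbola_rmv(ms, p["FSL"], p["RmVM"], p["RmT"])
    }
  }
  structure(list(kind = kind, parameters = p,
                 interval_days = interval_days, voxel_size = voxel_size,
                 noise = noise, rmv = fn),
            class = "mechanostat_truth")
}

#' Generate a trabecular-like binary phantom
#'
#' Seeded white noise is smoothed with a Gaussian (correlation length a few
#' voxels, mimicking trabecular thickness at ~10 um resolution) and
#' thresholded at the quantile that brings the bone volume fraction of the
#' largest 6-connected component within +/- 0.01 of the target; the
#' trabecular mask is the domain interior (a `margin`-voxel border is
#' excluded).
#'
#' @param shape integer length-3, volume dimensions `(z, y, x)`.
#' @param target_bvtv target bone volume fraction in the mask, in (0, 1).
#' @param seed integer seed (same seed, same phantom).
#' @param voxel_size voxel edge (um).
#' @param sigma smoothing standard deviation (voxels).
#' @param margin mask border width (voxels).
#' @param bone_margin border kept free of bone (voxels, > `margin`): the
#'   gap between bone and mask edge leaves headroom for surface growth
#'   when the phantom is advected.
#' @return list with `bone` ([binary_volume()]), `mask` ([binary_volume()])
#'   and `bvtv` (achieved fraction, measured over the bone-bearing
#'   interior).
#' @export
make_phantom <- function(shape, target_bvtv = 0.3, seed = 1L,
                         voxel_size = 10.5, sigma = 2, margin = 2L,
                         bone_margin = margin + 3L) {
  stopifnot(length(shape) == 3L, target_bvtv > 0, target_bvtv < 1,
            bone_margin >= margin)
  noise <- with_local_seed(derive_seed(seed, "phantom"),
                           array(stats::rnorm(prod(shape)), dim = shape))
  smooth <- gaussian_filter3(noise, sigma = sigma, truncate = 3)
  mask <- array(0L, dim = shape)
  zi <- (margin + 1L):(shape[1] - margin)
  yi <- (margin + 1L):(shape[2] - margin)
  xi <- (margin + 1L):(shape[3] - margin)
  mask[zi, yi, xi] <- 1L
  core <- array(FALSE, dim = shape)
  core[(bone_margin + 1L):(shape[1] - bone_margin),
       (bone_margin + 1L):(shape[2] - bone_margin),
       (bone_margin + 1L):(shape[3] - bone_margin)] <- TRUE
  inside <- core
  n_in <- sum(inside)
  build <- function(fill) {
    thr <- stats::quantile(smooth[inside], 1 - fill, names = FALSE)
    bin <- array(0L, dim = shape)
    bin[inside & smooth >= thr] <- 1L
    cl <- label_clusters(binary_volume(bin, voxel_size))
    if (length(cl$volumes) == 0L) return(list(bone = bin, bvtv = 0))
    keep <- which.max(cl$volumes)
    bone <- array(0L, dim = shape)
    bone[cl$labels == keep] <- 1L
    list(bone = bone, bvtv = sum(bone) / n_in)
  }
  # The largest-component volume is monotone in the fill fraction, but it
  # jumps discontinuously when blobs merge. Bisect to the largest fill
  # whose largest component stays below the target, then grow that
  # component by appending its highest-intensity adjacent marrow voxels:
  # connectivity is preserved by construction and the target is always
  # reached exactly (to the voxel).
  if (build(0.999)$bvtv < target_bvtv - 0.01) {
    stop("target BV/TV unreachable after component filtering",
         call. = FALSE)
  }
  lo <- 0; hi <- 0.999
  res <- list(bone = array(0L, dim = shape), bvtv = 0)
  for (i in 1:30) {
    fill <- (lo + hi) / 2
    cand <- build(fill)
    if (cand$bvtv <= target_bvtv) {
      lo <- fill
      res <- cand
    } else {
      hi <- fill
    }
  }
  target_n <- round(target_bvtv * n_in)
  for (round in 1:50) {
    deficit <- target_n - sum(res$bone)
    if (deficit <= 0L) break
    nb <- array(0L, dim = shape)
    for (k in seq_len(nrow(six_offsets))) {
      nb <- nb | shift3(res$bone, six_offsets[k, 1], six_offsets[k, 2],
                        six_offsets[k, 3])
    }
    cand_idx <- which(nb == 1L & res$bone == 0L & inside)
    if (length(cand_idx) == 0L) break
    cand_idx <- cand_idx[order(smooth[cand_idx], decreasing = TRUE)]
    res$bone[cand_idx[seq_len(min(deficit, length(cand_idx)))]] <- 1L
  }
  res$bvtv <- sum(res$bone) / n_in
  if (abs(res$bvtv - target_bvtv) > 0.01) {
    stop("target BV/TV unreachable after component filtering",
         call. = FALSE)
  }
  list(bone = binary_volume(res$bone, voxel_size),
       mask = binary_volume(mask, voxel_size),
       bvtv = res$bvtv)
}

#' Generate a smooth SED-like field for a phantom
#'
#' @param phantom output of [make_phantom()] (or any list with `bone` and
#'   `mask`).
#' @param mode `"ramp"` (affine in z), `"radial"` (affine in distance from
#'   the z axis through the volume center), or `"fe"` (delegate to
#'   [microfe_solve()] on the phantom with homogeneous material).
#' @param sed_min,sed_max field range in MPa for `ramp`/`radial`.
#' @param material a [material_map()] for `fe` mode.
#' @param axial_strain,bc_mode passed to [microfe_solve()] in `fe` mode.
#' @return a [scalar_volume()] of SED (MPa).
#' @export
make_signal_field <- function(phantom, mode = c("ramp", "radial", "fe"),
                              sed_min = 0, sed_max = 0.01,
                              material = material_map(),
                              axial_strain = 0.01, bc_mode = "affine") {
  mode <- match.arg(mode)
  bone <- phantom$bone
  d <- dim(bone$data)
  h <- bone$voxel_size
  if (mode == "ramp") {
    z_um <- (seq_len(d[1]) - 1) * h
    t <- if (d[1] > 1) z_um / max(z_um) else 0
    vals <- sed_min + (sed_max - sed_min) * t
    sed <- array(rep(vals, times = d[2] * d[3]), dim = d)
    return(scalar_volume(sed, h))
  }
  if (mode == "radial") {
    cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
    yy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
    xx <- rep(seq_len(d[3]), each = d[1] * d[2])
    r <- sqrt((yy - cy)^2 + (xx - cx)^2) * h
    t <- r / max(r)
    sed <- array(sed_min + (sed_max - sed_min) * t, dim = d)
    return(scalar_volume(sed, h))
  }
  E_field <- modulus_from_binary(bone, material)
  microfe_solve(E_field, poisson = material$poisson,
                axial_strain = axial_strain, bc_mode = bc_mode)$sed
}

#' Advect a bone surface under a mechanostat rule
#'
#' Per baseline surface voxel the mechanical signal is sampled with the
#' side convention of the field kind, converted to a target displacement
#' `d = RmV(signal) * interval_days / voxel_size` (voxels, plus seeded
#' Gaussian velocity noise), rounded to whole layers, and applied along the
#' surface normal direction approximated by the voxel's first marrow
#' 6-neighbor: formation adds voxels outward into marrow, resorption
#' removes bone inward. Two advancing fronts meeting merge (the collision
#' is counted, not double-added).
#'
#' @param baseline [binary_volume()] of baseline bone (inside the mask).
#' @param field a `signal_field` on the baseline grid.
#' @param truth a [mechanostat_truth()].
#' @param mask trabecular [binary_volume()] limiting growth.
#' @param seed integer seed for noise and probabilistic rounding.
#' @param rounding `"probabilistic"` (expected volume matches the target
#'   displacement exactly), `"floor"` or `"nearest"`.
#' @return list with `followup` ([binary_volume()]), `truth_table` (tibble:
#'   `z, y, x, signal, rmv_true, target_vox` exact signed displacement,
#'   `rounded_vox` the whole-layer realization of the target,
#'   `applied_vox` the layers actually added/removed after collisions and
#'   bounds, `event`) and `qc` (collision count).
#' @export
evolve_mechanostat <- function(baseline, field, truth, mask = NULL,
                               seed = 1L,
                               rounding = c("probabilistic", "floor",
                                            "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(baseline, "binary_volume"),
            inherits(field, "signal_field"),
            inherits(truth, "mechanostat_truth"))
  d <- dim(baseline$data)
  mask_arr <- if (is.null(mask)) array(1L, dim = d) else mask$data
  surf <- surface_mask(baseline)
  idx <- which(surf$data == 1L)
  coord <- arrayInd(idx, d)
  tbl <- tibble::tibble(z = coord[, 1], y = coord[, 2], x = coord[, 3],
                        event = factor("quiescence",
                                       levels = c("formation", "quiescence",
                                                  "resorption")),
                        distance_vox = 0, cluster_id = NA_integer_,
                        signal = NA_real_)
  tbl <- sample_surface_signal(tbl, field, baseline)
  v <- truth$rmv(tbl$signal)
  scale <- truth$interval_days / truth$voxel_size
  target <- v * scale
  if (truth$noise > 0) {
    target <- target + with_local_seed(
      derive_seed(seed, "noise"),
      stats::rnorm(length(target), sd = truth$noise * scale))
  }
  n_layers <- switch(rounding,
    probabilistic = {
      u <- with_local_seed(derive_seed(seed, "round"),
                           stats::runif(length(target)))
      sign(target) * (floor(abs(target)) + (u < abs(target) %% 1))
    },
    floor = sign(target) * floor(abs(target)),
    nearest = round(target)
  )
  n_layers <- as.integer(n_layers)

  vol <- baseline$data
  strides <- c(1L, d[1], d[1] * d[2])
  applied <- integer(length(idx))
  collisions <- 0L
  # deterministic processing order: linear index of the surface voxel
  ord <- order(idx)
  for (s in ord) {
    n <- n_layers[s]
    if (n == 0L) next
    p <- c(tbl$z[s], tbl$y[s], tbl$x[s])
    # outward normal directions ~ marrow 6-neighbors of the baseline
    # image, in fixed offset order; growth blocked along one direction
    # falls through to the next (fronts meeting merge, counted below)
    dirs <- list()
    for (k in seq_len(nrow(six_offsets))) {
      q <- p + six_offsets[k, ]
      if (all(q >= 1L) && all(q <= d) &&
          baseline$data[q[1], q[2], q[3]] == 0L) {
        dirs[[length(dirs) + 1L]] <- six_offsets[k, ]
      }
    }
    if (length(dirs) == 0L) next   # marrow only out of bounds
    if (n > 0L) {
      remaining <- n
      for (dir in dirs) {
        if (remaining == 0L) break
        for (k in seq_len(remaining)) {
          q <- p + k * dir
          if (any(q < 1L) || any(q > d) ||
              mask_arr[q[1], q[2], q[3]] == 0L) break
          if (vol[q[1], q[2], q[3]] == 1L) { collisions <- collisions + 1L; break }
          vol[q[1], q[2], q[3]] <- 1L
          applied[s] <- applied[s] + 1L
        }
        remaining <- n - applied[s]
      }
    } else {
      dir <- dirs[[1]]
      for (k in seq_len(-n)) {
        q <- p - (k - 1L) * dir
        if (any(q < 1L) || any(q > d)) break
        if (vol[q[1], q[2], q[3]] == 0L) { collisions <- collisions + 1L; next }
        vol[q[1], q[2], q[3]] <- 0L
        applied[s] <- applied[s] - 1L
      }
    }
  }
  event <- rep("quiescence", length(idx))
  event[applied > 0L] <- "formation"
  event[applied < 0L] <- "resorption"
  truth_table <- tibble::tibble(
    z = tbl$z, y = tbl$y, x = tbl$x, signal = tbl$signal,
    rmv_true = v, target_vox = target, rounded_vox = n_layers,
    applied_vox = applied,
    event = factor(event, levels = c("formation", "quiescence",
                                     "resorption"))
  )
  list(followup = binary_volume(vol, baseline$voxel_size),
       truth_table = truth_table,
       qc = list(collisions = collisions))
}

#' Generate one complete synthetic sample
#'
#' Convenience wrapper: phantom + SED ramp + effective-strain signal field
#' + mechanostat surface advection, returning everything both the
#' generator and the recovery pipeline need.
#'
#' @param seed integer seed.
#' @param truth a [mechanostat_truth()].
#' @param shape phantom dimensions.
#' @param target_bvtv bone volume fraction target.
#' @param strain_max maximum effective strain of the ramp (microstrain) at
#'   the top of the volume.
#' @param E_bone bone modulus (MPa) used to convert the SED ramp to
#'   effective strain.
#' @param sigma phantom smoothing length (voxels); sets trabecular
#'   thickness and marrow spacing.
#' @param field_mode passed to [make_signal_field()].
#' @return list with `baseline`, `followup`, `mask`, `field` (effective
#'   strain `signal_field`), `truth_table`, `truth`, `qc`.
#' @export
synth_sample <- function(seed, truth, shape = c(48L, 48L, 48L),
                         target_bvtv = 0.25, strain_max = 600,
                         E_bone = 14800, field_mode = "ramp", sigma = 2.5) {
  ph <- make_phantom(shape, target_bvtv = target_bvtv, seed = seed,
                     voxel_size = truth$voxel_size, sigma = sigma)
  if (field_mode == "ramp") {
    # SED quadratic in z so that effective strain is linear in z: the
    # study conditions are phrased in effective strain, and a linear
    # strain ramp populates all strain bins evenly
    d <- dim(ph$bone$data)
    t <- if (d[1] > 1) (seq_len(d[1]) - 1) / (d[1] - 1) else 0
    eps <- strain_max * t * 1e-6
    sed_vals <- E_bone / 2 * eps^2
    sed <- scalar_volume(array(rep(sed_vals, times = d[2] * d[3]), dim = d),
                         ph$bone$voxel_size)
  } else {
    sed_max <- E_bone / 2 * (strain_max * 1e-6)^2
    sed <- make_signal_field(ph, mode = field_mode, sed_min = 0,
                             sed_max = sed_max)
  }
  field <- effective_strain_field(sed, E_bone)
  ev <- evolve_mechanostat(ph$bone, field, truth, mask = ph$mask,
                           seed = derive_seed(seed, "evolve"))
  list(baseline = ph$bone, followup = ev$followup, mask = ph$mask,
       field = field, truth_table = ev$truth_table, truth = truth,
       qc = ev$qc)
}
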