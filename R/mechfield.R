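#' Mechanical signal fields
#'
#' The local mechanical environment driving (re)modeling is described by one
#' of three voxel fields derived from a linear-elastic FE solution: strain
#' energy density (SED, MPa), effective strain (microstrain), or the
#' Euclidean norm of the SED gradient (MPa/um, a proxy for interstitial
#' fluid flow). SED and effective strain are sampled on the bone side of the
#' bone/marrow interface; the SED gradient norm on the marrow side.
#'
#' @name mechfield
NULL

#' Construct a signal field
#'
#' @param data a [scalar_volume()] with non-negative values.
#' @param kind one of `"sed"` (MPa), `"effective_strain"` (microstrain),
#'   `"grad_sed_norm"` (MPa/um).
#' @return a `signal_field` object; `sampling_side` is `"bone"` for SED and
#'   effective strain, `"marrow"` for the gradient norm.
#' @export
signal_field <- function(data, kind = c("sed", "effective_strain",
                                        "grad_sed_norm")) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "voxel_volume"))
  if (any(data$data < 0)) {
    stop("signal fields must be non-negative", call. = FALSE)
  }
  structure(
    list(
      data = data$data, voxel_size = data$voxel_size, kind = kind,
      sampling_side = if (kind == "grad_sed_norm") "marrow" else "bone"
    ),
    class = c("signal_field", "voxel_volume")
  )
}

#' Effective strain from SED and Young's modulus
#'
#' The SED-derived scalar strain measure `sqrt(2 U / E)`, reported in
#' microstrain. It inverts `U = E eps^2 / 2`, accounting voxel-wise for
#' differences in tissue modulus.
#'
#' @param sed [scalar_volume()] of strain energy density (MPa), >= 0.
#' @param E_field [scalar_volume()] of Young's modulus (MPa), > 0, or a
#'   single number for homogeneous material.
#' @return a `signal_field` of kind `"effective_strain"` (microstrain).
#' @export
effective_strain_field <- function(sed, E_field) {
  stopifnot(inherits(sed, "voxel_volume"))
  if (any(sed$data < 0)) stop("negative SED", call. = FALSE)
  E <- if (is.numeric(E_field) && is.null(dim(E_field))) {
    array(E_field, dim = dim(sed$data))
  } else {
    stop_if_grid_mismatch(sed, E_field, "SED/modulus")
    E_field$data
  }
  if (any(E <= 0)) stop("zero or negative Young's modulus", call. = FALSE)
  eps <- sqrt(2 * sed$data / E) * 1e6
  signal_field(scalar_volume(eps, sed$voxel_size), "effective_strain")
}

#' Norm of the SED gradient
#'
#' Central differences in the interior, one-sided differences at the
#' boundaries, spacing equal to the voxel size; the Euclidean norm of the
#' three components is returned in MPa/um.
#'
#' @param sed [scalar_volume()] of SED (MPa); every axis must have >= 3
#'   voxels.
#' @return a `signal_field` of kind `"grad_sed_norm"`.
#' @export
sed_gradient_norm <- function(sed) {
  stopifnot(inherits(sed, "voxel_volume"))
  if (any(dim(sed$data) < 3L)) {
    stop("degenerate dimensions: need >= 3 voxels per axis", call. = FALSE)
  }
  h <- sed$voxel_size
  sq <- array(0, dim = dim(sed$data))
  for (axis in 1:3) {
    sq <- sq + axis_gradient(sed$data, axis, h)^2
  }
  signal_field(scalar_volume(sqrt(sq), h), "grad_sed_norm")
}

axis_gradient <- function(arr, axis, h) {
  n <- dim(arr)[axis]
  take <- function(i) switch(axis,
    arr[i, , , drop = FALSE], arr[, i, , drop = FALSE],
    arr[, , i, drop = FALSE])
  g <- array(0, dim = dim(arr))
  put <- function(i, value) {
    if (axis == 1) g[i, , ] <<- value
    else if (axis == 2) g[, i, ] <<- value
    else g[, , i] <<- value
  }
  put(1, (take(2) - take(1)) / h)
  put(n, (take(n) - take(n - 1)) / h)
  if (n > 2) {
    mid <- 2:(n - 1)
    val <- (take(mid + 1) - take(mid - 1)) / (2 * h)
    if (axis == 1) g[mid, , ] <- val
    else if (axis == 2) g[, mid, ] <- val
    else g[, , mid] <- val
  }
  g
}

#' Material map for voxel FE
#'
#' Homogeneous mode assigns one modulus to bone and one to marrow;
#' heterogeneous mode converts calibrated density to modulus through a
#' linear relation with a lower clamp.
#'
#' @param mode `"homogeneous"` or `"heterogeneous"`.
#' @param E_bone,E_marrow Young's moduli in MPa (defaults 14800 and 2).
#' @param poisson Poisson's ratio in `[0, 0.5)`.
#' @param density_slope,density_intercept calibration constants for
#'   heterogeneous mode, MPa per (mgHA/cm^3) and MPa; no defaults, they are
#'   an external calibration.
#' @param E_min lower clamp for the heterogeneous modulus (MPa, default 2).
#' @return a `material_map` list.
#' @export
material_map <- function(mode = c("homogeneous", "heterogeneous"),
                         E_bone = 14800, E_marrow = 2, poisson = 0.3,
                         density_slope = NULL, density_intercept = NULL,
                         E_min = 2) {
  mode <- match.arg(mode)
  stopifnot(E_bone > 0, E_marrow > 0, E_min > 0,
            poisson >= 0, poisson < 0.5)
  if (mode == "heterogeneous" &&
      (is.null(density_slope) || is.null(density_intercept))) {
    stop("heterogeneous mode requires density_slope and density_intercept",
         call. = FALSE)
  }
  structure(list(mode = mode, E_bone = E_bone, E_marrow = E_marrow,
                 poisson = poisson, density_slope = density_slope,
                 density_intercept = density_intercept, E_min = E_min),
            class = "material_map")
}

#' Convert density to Young's modulus (heterogeneous material)
#'
#' `E = max(slope * density + intercept, E_min)` voxel-wise.
#'
#' @param density [scalar_volume()] of calibrated density (mgHA/cm^3).
#' @param map a [material_map()] in heterogeneous mode.
#' @return [scalar_volume()] of Young's modulus (MPa).
#' @export
density_to_modulus <- function(density, map) {
  stopifnot(inherits(density, "voxel_volume"), inherits(map, "material_map"))
  if (map$mode != "heterogeneous") {
    stop("density_to_modulus requires a heterogeneous material map",
         call. = FALSE)
  }
  E <- pmax(map$density_slope * density$data + map$density_intercept,
            map$E_min)
  scalar_volume(E, density$voxel_size)
}

#' Modulus field from a binary image (homogeneous material)
#'
#' @param bone a [binary_volume()].
#' @param map a [material_map()] (homogeneous mode).
#' @return [scalar_volume()] with `E_bone` at bone voxels, `E_marrow`
#'   elsewhere.
#' @export
modulus_from_binary <- function(bone, map = material_map()) {
  stopifnot(inherits(bone, "binary_volume"), inherits(map, "material_map"))
  E <- ifelse(bone$data == 1L, map$E_bone, map$E_marrow)
  scalar_volume(E, bone$voxel_size)
}

#' Rescale a signal field to a target applied force
#'
#' The FE problem is linear elastic, so displacements (and strains) scale
#' linearly with the applied force while energy quantities (SED and its
#' gradient norm) scale quadratically: with `k = F_target / F_fe`,
#' effective strain scales by `k` and SED / grad-SED by `k^2`.
#'
#' @param field a `signal_field`.
#' @param F_fe force corresponding to the FE solution (N), > 0.
#' @param F_target force to rescale to (N), > 0 (e.g. 8 N for loaded
#'   groups, 4 N physiological for sham).
#' @return the rescaled `signal_field`.
#' @export
rescale_to_force <- function(field, F_fe, F_target) {
  stopifnot(inherits(field, "signal_field"))
  if (F_fe <= 0 || F_target <= 0) {
    stop("forces must be positive", call. = FALSE)
  }
  k <- F_target / F_fe
  factor <- if (field$kind == "effective_strain") k else k^2
  field$data <- field$data * factor
  field
}

#' Sample a signal field on the correct side of the bone surface
#'
#' Bone-side signals (SED, effective strain) are read at the surface voxel
#' itself; the marrow-side signal (grad-SED norm) is averaged over the
#' surface voxel's marrow 6-neighbors.
#'
#' @param table a surface sample table from [build_surface_table()].
#' @param field a `signal_field` on the baseline grid.
#' @param bone the baseline trabecular [binary_volume()] (defines which
#'   neighbors are marrow).
#' @return the table with its `signal` column filled.
#' @export
sample_surface_signal <- function(table, field, bone) {
  stopifnot(inherits(field, "signal_field"), inherits(bone, "binary_volume"))
  d <- dim(field$data)
  if (!identical(d, dim(bone$data))) {
    stop("field/bone shape mismatch", call. = FALSE)
  }
  strides <- c(1L, d[1], d[1] * d[2])
  lin <- table$z + (table$y - 1L) * strides[2] + (table$x - 1L) * strides[3]
  if (field$sampling_side == "bone") {
    table$signal <- field$data[lin]
    return(table)
  }
  total <- numeric(nrow(table))
  count <- integer(nrow(table))
  for (k in seq_len(nrow(six_offsets))) {
    nz <- table$z + six_offsets[k, 1]
    ny <- table$y + six_offsets[k, 2]
    nx <- table$x + six_offsets[k, 3]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] &
      nx >= 1L & nx <= d[3]
    nlin <- nz[ok] + (ny[ok] - 1L) * strides[2] + (nx[ok] - 1L) * strides[3]
    marrow <- bone$data[nlin] == 0L
    add <- numeric(nrow(table))
    inc <- integer(nrow(table))
    add[ok][marrow] <- field$data[nlin][marrow]
    inc[ok][marrow] <- 1L
    total <- total + add
    count <- count + inc
  }
  if (any(count == 0L)) {
    stop("surface voxel with no marrow 6-neighbor: inputs inconsistent",
         call. = FALSE)
  }
  table$signal <- total / count
  table
}
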