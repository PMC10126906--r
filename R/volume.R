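#' Voxel volumes
#'
#' 3D voxel grids with an isotropic voxel size are the universal currency of
#' the pipeline. A `scalar_volume` holds real values (e.g. density in
#' mgHA/cm^3, strain energy density in MPa); a `binary_volume` holds a 0/1
#' segmentation. Both are thin S3 wrappers around a base 3D array stored in
#' `(z, y, x)` axis order, with the voxel edge length in micrometres kept as
#' an attribute. All readers convert into this one convention.
#'
#' @param data numeric 3D array; for binary volumes values must be 0/1 (a
#'   logical array is accepted and coerced).
#' @param voxel_size voxel edge length in micrometres (isotropic), > 0.
#' @return An object of class `scalar_volume` or `binary_volume` (both also
#'   inherit from `voxel_volume`).
#' @examples
#' v <- scalar_volume(array(runif(27), c(3, 3, 3)), voxel_size = 10.5)
#' dim(v$data)
#' @name voxel_volume
NULL

#' @rdname voxel_volume
#' @export
scalar_volume <- function(data, voxel_size) {
  data <- as_array3(data)
  check_voxel_size(voxel_size)
  if (!all(is.finite(data))) {
    stop("scalar_volume: all values must be finite", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size)),
    class = c("scalar_volume", "voxel_volume")
  )
}

#' @rdname voxel_volume
#' @export
binary_volume <- function(data, voxel_size) {
  data <- as_array3(data)
  check_voxel_size(voxel_size)
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  }
  if (!all(data %in% c(0L, 1L))) {
    stop("binary_volume: values must be 0 or 1", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size)),
    class = c("binary_volume", "voxel_volume")
  )
}

as_array3 <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("non-3D data: a voxel volume requires a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) {
    stop("all three dimensions must be >= 1", call. = FALSE)
  }
  data
}

check_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be a single positive number (micrometres)",
         call. = FALSE)
  }
}

#' @export
print.voxel_volume <- function(x, ...) {
  kind <- if (inherits(x, "binary_volume")) "binary" else "scalar"
  d <- dim(x$data)
  cat(sprintf("<%s volume> %d x %d x %d voxels (z,y,x), %.4g um/voxel\n",
              kind, d[1], d[2], d[3], x$voxel_size))
  if (kind == "binary") {
    cat(sprintf("  foreground: %d voxels (%.1f%%)\n", sum(x$data),
                100 * mean(x$data)))
  } else {
    cat(sprintf("  range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Coerce a scalar volume to binary by thresholding
#'
#' @param vol a `scalar_volume`.
#' @param threshold inclusive threshold: output is 1 where `vol >= threshold`.
#' @return a `binary_volume`.
#' @export
threshold_volume <- function(vol, threshold) {
  stopifnot(inherits(vol, "voxel_volume"))
  binary_volume(vol$data >= threshold, vol$voxel_size)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop(sprintf("shape/voxel-size mismatch between %s", what), call. = FALSE)
  }
  invisible(TRUE)
}
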