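#' Read a voxel volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mha`, and `.mhd` with a
#' separate raw file) and multi-page TIFF stacks. The volume is returned in
#' the package's internal `(z, y, x)` axis order with the voxel size in
#' micrometres taken from the header; TIFF carries no 3D spacing so
#' `voxel_size` must be supplied explicitly.
#'
#' @param path path to the image file.
#' @param format one of `"nifti"`, `"metaimage"`, `"tiff_stack"`; by default
#'   inferred from the file extension.
#' @param voxel_size explicit voxel size override in micrometres. Required
#'   for TIFF; for NIfTI/MetaImage it overrides the header value if given.
#' @param binary if `TRUE`, return a [binary_volume()] (values must be 0/1).
#' @return a [scalar_volume()] or [binary_volume()].
#' @export
read_volume <- function(path, format = NULL, voxel_size = NULL,
                        binary = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("nifti", "metaimage", "tiff_stack"))
  res <- switch(format,
    nifti = read_nifti_volume(path),
    metaimage = read_metaimage_volume(path),
    tiff_stack = read_tiff_volume(path)
  )
  vs <- voxel_size %||% res$voxel_size
  if (is.null(vs)) {
    stop("voxel size missing from header and no explicit override given",
         call. = FALSE)
  }
  if (binary) binary_volume(res$data, vs) else scalar_volume(res$data, vs)
}

#' Write a voxel volume to disk
#'
#' @param vol a [scalar_volume()] or [binary_volume()].
#' @param path output path; extension decides the container unless `format`
#'   is given. NIfTI stores the voxel size in micrometre units; MetaImage in
#'   `ElementSpacing`; TIFF stores no spacing (keep track of it yourself).
#' @param format one of `"nifti"`, `"metaimage"`, `"tiff_stack"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "voxel_volume"))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("nifti", "metaimage", "tiff_stack"))
  switch(format,
    nifti = write_nifti_volume(vol, path),
    metaimage = write_metaimage_volume(vol, path),
    tiff_stack = write_tiff_volume(vol, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lower)) return("metaimage")
  if (grepl("\\.(tif|tiff)$", lower)) return("tiff_stack")
  stop(sprintf("cannot infer volume format from extension of '%s'", path),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- NIfTI (RNifti) -------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("non-3D data in NIfTI file", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  units <- tryCatch(RNifti::pixunits(img), error = function(e) "unknown")
  scale <- if (any(units == "mm")) 1000 else if (any(units == "m")) 1e6 else 1
  vs <- if (length(pd) >= 1 && is.finite(pd[1]) && pd[1] > 0) {
    pd[1] * scale
  } else {
    NULL
  }
  # stored (x, y, z); internal convention is (z, y, x)
  list(data = aperm(arr, c(3, 2, 1)), voxel_size = vs)
}

write_nifti_volume <- function(vol, path) {
  arr <- aperm(vol$data, c(3, 2, 1))
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vol$voxel_size, 3)
  RNifti::pixunits(img) <- c("um", "s")
  RNifti::writeNifti(img, path)
}

## ---- MetaImage (minimal local reader/writer) ------------------------------

# MetaImage is a plain text header followed by (or pointing at) raw voxel
# data, x fastest. Only the fields needed for dense 3D grids are handled.

read_metaimage_volume <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.mhd$", lower)) {
    header <- parse_mha_header(readLines(path, warn = FALSE))
    datafile <- header$ElementDataFile
    if (is.null(datafile) || identical(toupper(datafile), "LOCAL")) {
      stop("MetaImage .mhd must reference an external ElementDataFile",
           call. = FALSE)
    }
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path)) {
      stop(sprintf("MetaImage raw file not found: %s", raw_path),
           call. = FALSE)
    }
    payload <- readBin(raw_path, "raw", n = file.size(raw_path))
  } else {
    bytes <- readBin(path, "raw", n = file.size(path))
    split <- split_mha_local(bytes)
    header <- parse_mha_header(split$header_lines)
    payload <- split$payload
  }
  decode_mha(header, payload)
}

split_mha_local <- function(bytes) {
  # header ends at the newline terminating the ElementDataFile line
  marker <- charToRaw("ElementDataFile")
  hit <- find_raw(bytes, marker)
  if (is.na(hit)) stop("malformed MetaImage: no ElementDataFile", call. = FALSE)
  nl <- which(bytes[hit:length(bytes)] == as.raw(10L))[1]
  if (is.na(nl)) stop("malformed MetaImage header", call. = FALSE)
  end <- hit + nl - 1L
  header_txt <- rawToChar(bytes[seq_len(end)])
  list(
    header_lines = strsplit(header_txt, "\n", fixed = TRUE)[[1]],
    payload = bytes[seq.int(end + 1L, length(bytes))]
  )
}

find_raw <- function(haystack, needle) {
  starts <- which(haystack == needle[1])
  for (s in starts) {
    if (s + length(needle) - 1L <= length(haystack) &&
        all(haystack[s + seq_along(needle) - 1L] == needle)) {
      return(s)
    }
  }
  NA_integer_
}

parse_mha_header <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  header <- list()
  for (pair in kv) {
    if (length(pair) < 2) next
    header[[trimws(pair[[1]])]] <- trimws(paste(pair[-1], collapse = "="))
  }
  header
}

decode_mha <- function(header, payload) {
  ndims <- as.integer(header$NDims %||% "0")
  if (!identical(ndims, 3L)) {
    stop("non-3D data in MetaImage file", call. = FALSE)
  }
  dims <- as.integer(strsplit(header$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(header$ElementSpacing)) {
    as.numeric(strsplit(header$ElementSpacing, "\\s+")[[1]])[1]
  } else {
    NULL
  }
  type <- header$ElementType %||% "MET_FLOAT"
  info <- switch(type,
    MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
    MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
    MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
    MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
    MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE),
    stop(sprintf("unsupported MetaImage ElementType: %s", type),
         call. = FALSE)
  )
  msb <- identical(header$BinaryDataByteOrderMSB %||%
                     header$ElementByteOrderMSB %||% "False", "True")
  n <- prod(dims)
  vals <- readBin(payload, info$what, n = n, size = info$size,
                  signed = info$signed,
                  endian = if (msb) "big" else "little")
  if (length(vals) != n) {
    stop("MetaImage payload shorter than DimSize promises", call. = FALSE)
  }
  arr <- array(vals, dim = dims)            # (x, y, z), x fastest
  list(data = aperm(arr, c(3, 2, 1)), voxel_size = spacing)
}

write_metaimage_volume <- function(vol, path) {
  if (!grepl("\\.mha$", tolower(path))) {
    stop("MetaImage writing supports local-data .mha only", call. = FALSE)
  }
  is_binary <- inherits(vol, "binary_volume")
  type <- if (is_binary) "MET_UCHAR" else "MET_DOUBLE"
  d <- dim(vol$data)                        # (z, y, x)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementSpacing = %s %s %s",
            format(vol$voxel_size, digits = 17),
            format(vol$voxel_size, digits = 17),
            format(vol$voxel_size, digits = 17)),
    sprintf("ElementType = %s", type),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  vals <- as.vector(aperm(vol$data, c(3, 2, 1)))
  if (is_binary) {
    writeBin(as.raw(vals), con)
  } else {
    writeBin(as.numeric(vals), con, size = 8L, endian = "little")
  }
}

## ---- TIFF stacks ----------------------------------------------------------

read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    stop("non-3D data: TIFF has a single page, expected a stack",
         call. = FALSE)
  }
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
    p
  })
  d <- dim(mats[[1]])
  arr <- array(0, dim = c(length(mats), d[1], d[2]))  # (z, y, x)
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  list(data = arr, voxel_size = NULL)
}

write_tiff_volume <- function(vol, path) {
  rng <- range(vol$data)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("TIFF stacks store samples in [0, 1]; rescale or use NIfTI/MetaImage",
         call. = FALSE)
  }
  is_binary <- inherits(vol, "binary_volume")
  pages <- lapply(seq_len(dim(vol$data)[1]), function(i) {
    m <- vol$data[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(vol$data)[2])
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (is_binary) 8L else 32L)
}

## ---- Preprocessing --------------------------------------------------------

#' Gaussian filter and binarize a density image
#'
#' Standard preprocessing for in vivo micro-CT density images: a separable 3D
#' Gaussian filter followed by a global threshold. Defaults follow common
#' practice for 10.5 um murine scans (sigma 1.2 voxels, kernel truncated at 1
#' sigma, threshold 580 mgHA/cm^3). The threshold is inclusive (`>=`) and the
#' filter uses symmetric reflect padding at the borders; both conventions are
#' documented choices, tested in the suite.
#'
#' @param vol a [scalar_volume()] (calibrated density, mgHA/cm^3).
#' @param sigma Gaussian standard deviation in voxels (> 0).
#' @param truncate kernel support in standard deviations (> 0); the discrete
#'   kernel radius is `ceiling(truncate * sigma)`.
#' @param threshold binarization threshold in the units of `vol`.
#' @return a [binary_volume()].
#' @export
gaussian_binarize <- function(vol, sigma = 1.2, truncate = 1,
                              threshold = 580) {
  stopifnot(inherits(vol, "voxel_volume"))
  smoothed <- gaussian_filter3(vol$data, sigma = sigma, truncate = truncate)
  binary_volume(smoothed >= threshold, vol$voxel_size)
}

#' Separable 3D Gaussian filter with reflect padding
#'
#' @param arr numeric 3D array.
#' @param sigma standard deviation in voxels.
#' @param truncate kernel support in sigmas; radius = `ceiling(truncate*sigma)`.
#' @return filtered array, same shape.
#' @export
gaussian_filter3 <- function(arr, sigma = 1.2, truncate = 1) {
  if (sigma <= 0 || truncate <= 0) {
    stop("sigma and truncate must be positive", call. = FALSE)
  }
  if (!all(is.finite(arr))) {
    stop("non-finite input values", call. = FALSE)
  }
  r <- ceiling(truncate * sigma)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  for (axis in 1:3) arr <- convolve_axis(arr, w, axis)
  arr
}

# 1D convolution along `axis` of a 3D array, symmetric reflect padding
# (edge value included in the mirror, scipy-style "reflect").
convolve_axis <- function(arr, w, axis) {
  n <- dim(arr)[axis]
  r <- (length(w) - 1L) / 2L
  idx <- reflect_index(n, r)
  out <- array(0, dim = dim(arr))
  for (j in seq_along(w)) {
    sel <- idx[seq_len(n) + (j - 1L)]
    shifted <- switch(axis,
      arr[sel, , , drop = FALSE],
      arr[, sel, , drop = FALSE],
      arr[, , sel, drop = FALSE]
    )
    out <- out + w[j] * shifted
  }
  out
}

reflect_index <- function(n, r) {
  # indices for positions (1-r)..(n+r) under symmetric reflection
  pos <- seq.int(1L - r, n + r)
  period <- 2L * n
  m <- ((pos - 1L) %% period + period) %% period  # 0..2n-1
  ifelse(m < n, m + 1L, period - m)
}
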