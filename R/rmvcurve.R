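#' (Re)modeling velocity curves
#'
#' A 2D histogram relates the mechanical signal (horizontal axis, capped at
#' the 99th percentile of all observed values and binned at 1% of the cap)
#' to the scaled (re)modeling distance (vertical axis, binned at 1% of the
#' maximum absolute value observed, sign restored). The per-signal-bin
#' weighted average of the binned distances -- quiescent surface voxels
#' entering as zero -- is converted to a surface velocity in um/day by
#' multiplying by the voxel size and dividing by the scan interval.
#'
#' @param table a surface sample table with `event`, `distance_vox` and
#'   `signal` filled.
#' @param voxel_size voxel edge length (um).
#' @param interval_days days between the two time points (> 0).
#' @param n_bins number of signal bins (default 100).
#' @param cap signal cap; defaults to the 99th percentile of `table$signal`.
#'   Supply explicitly to place several samples on a shared bin grid.
#' @param distance_binning `"binned"` (default: snap distances to the center
#'   of their 1%-of-max bin before averaging) or `"raw"`.
#' @return an object of class `rmv_curve`: tibble with `bin`, `signal`
#'   (bin-center, signal units), `rmv` (um/day, `NA` where empty), `counts`,
#'   `n_samples`; attributes `cap`, `voxel_size`, `interval_days`.
#' @export
compute_rmv_curve <- function(table, voxel_size = attr(table, "voxel_size"),
                              interval_days, n_bins = 100L, cap = NULL,
                              distance_binning = c("binned", "raw")) {
  distance_binning <- match.arg(distance_binning)
  if (nrow(table) == 0L) stop("empty surface table", call. = FALSE)
  if (is.null(voxel_size)) stop("voxel_size required", call. = FALSE)
  if (interval_days <= 0) stop("interval_days must be > 0", call. = FALSE)
  if (any(is.na(table$signal))) {
    stop("signal column contains NA; run sample_surface_signal() first",
         call. = FALSE)
  }
  cap <- cap %||% stats::quantile(table$signal, 0.99, names = FALSE)
  bin <- signal_bin(table$signal, cap, n_bins)
  dist <- table$distance_vox
  if (distance_binning == "binned") {
    dmax <- max(abs(dist))
    if (dmax > 0) {
      width <- dmax / 100
      db <- floor(abs(dist) / width)
      db[abs(dist) == dmax] <- 99           # top value belongs to last bin
      snapped <- (db + 0.5) * width * sign(dist)
      snapped[dist == 0] <- 0
      dist <- snapped
    }
  }
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(dist[bin == b]), 0)
  sig_sums <- vapply(seq_len(n_bins), function(b) sum(table$signal[bin == b]), 0)
  mean_dist <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  centers <- (seq_len(n_bins) - 0.5) * cap / n_bins
  # abscissa: observed mean signal of the bin (falls back to the bin
  # center when empty) -- more faithful than the nominal center when the
  # signal takes few distinct values
  mean_sig <- ifelse(counts > 0, sig_sums / pmax(counts, 1L), centers)
  curve <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_center = centers,
    signal = mean_sig,
    rmv = mean_dist * voxel_size / interval_days,
    counts = counts,
    n_samples = as.integer(counts > 0)
  )
  new_rmv_curve(curve, cap, voxel_size, interval_days)
}

new_rmv_curve <- function(curve, cap, voxel_size, interval_days) {
  structure(curve, cap = cap, voxel_size = voxel_size,
            interval_days = interval_days,
            class = c("rmv_curve", class(tibble::tibble())))
}

#' Group-average (re)modeling velocity curve
#'
#' Builds per-sample curves on a shared bin grid (cap = 99th percentile of
#' the pooled signal values) and averages them bin-wise, unweighted, over
#' the samples that have observations in the bin. Bins with fewer than
#' `min_samples` contributing samples are masked (`rmv = NA`), so that the
#' group curve only reports signal levels seen in at least that many
#' animals.
#'
#' @param tables list of per-sample surface tables (signal filled).
#' @param voxel_size voxel edge length (um), shared by all samples.
#' @param interval_days scan interval (days).
#' @param min_samples minimum number of contributing samples per bin
#'   (default 3).
#' @param n_bins number of signal bins.
#' @param distance_binning passed to [compute_rmv_curve()].
#' @return an `rmv_curve`; `n_samples` counts contributing samples per bin.
#' @export
group_average_curve <- function(tables, voxel_size, interval_days,
                                min_samples = 3L, n_bins = 100L,
                                distance_binning = c("binned", "raw")) {
  distance_binning <- match.arg(distance_binning)
  if (length(tables) < min_samples) {
    stop(sprintf("need at least %d samples, got %d", min_samples,
                 length(tables)), call. = FALSE)
  }
  pooled <- unlist(lapply(tables, function(t) t$signal))
  if (any(is.na(pooled))) {
    stop("signal column contains NA in at least one sample", call. = FALSE)
  }
  cap <- stats::quantile(pooled, 0.99, names = FALSE)
  curves <- lapply(tables, compute_rmv_curve, voxel_size = voxel_size,
                   interval_days = interval_days, n_bins = n_bins, cap = cap,
                   distance_binning = distance_binning)
  rmv_mat <- sapply(curves, function(cv) cv$rmv)
  count_mat <- sapply(curves, function(cv) cv$counts)
  contributing <- rowSums(count_mat > 0)
  rmv <- rowMeans(rmv_mat, na.rm = TRUE)
  rmv[contributing < min_samples] <- NA_real_
  if (all(is.na(rmv))) {
    stop("fewer than min_samples samples contribute in every bin",
         call. = FALSE)
  }
  centers <- (seq_len(n_bins) - 0.5) * cap / n_bins
  sig_mat <- sapply(curves, function(cv) cv$signal)
  sig_w <- rowSums(sig_mat * count_mat)
  total_counts <- rowSums(count_mat)
  mean_sig <- ifelse(total_counts > 0, sig_w / pmax(total_counts, 1L),
                     centers)
  curve <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_center = centers,
    signal = mean_sig,
    rmv = rmv,
    counts = as.integer(total_counts),
    n_samples = as.integer(contributing)
  )
  new_rmv_curve(curve, cap, voxel_size, interval_days)
}

#' Plot a (re)modeling velocity curve, optionally with fits
#'
#' @param object an `rmv_curve`.
#' @param fits optional named list of fitted objects ([fit_piecewise()] /
#'   [fit_hyperbola()] results) to overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rmv_curve
#' @export
autoplot.rmv_curve <- function(object, fits = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df[!is.na(df$rmv), ],
                       ggplot2::aes(x = .data$signal, y = .data$rmv)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "mechanical signal", y = "RmV (um/day)") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    grid <- seq(min(df$signal), max(df$signal), length.out = 400)
    for (nm in names(fits)) {
      fd <- tibble::tibble(signal = grid,
                           rmv = predict_mechanostat(fits[[nm]], grid),
                           fit = nm)
      p <- p + ggplot2::geom_line(
        data = fd, ggplot2::aes(x = .data$signal, y = .data$rmv,
                                colour = .data$fit))
    }
  }
  p
}
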