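#' Balanced bootstrap and loading-frequency regression
#'
#' Parameter uncertainty for group-level mechanostat fits is characterized
#' with a balanced bootstrap: across all replicates each sample appears
#' exactly `n_rep` times, removing the extra Monte-Carlo variance of plain
#' resampling. Frequency dependence of a parameter is summarized by the
#' logarithmic regression `y = y0 + a ln(f)` fitted to the bootstrap
#' medians of the cyclically loaded groups.
#'
#' @name freqstats
NULL

#' Balanced bootstrap index sets
#'
#' Concatenates `n_rep` copies of the sample ids, permutes them uniformly
#' with a seeded generator, and splits the permutation into `n_rep` blocks
#' of size `n`: each id appears exactly `n_rep` times overall.
#'
#' @param sample_ids vector of n >= 2 identifiers.
#' @param n_rep number of replicates (default 2500).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return a list of `n_rep` vectors of `n` ids each.
#' @export
balanced_bootstrap_replicates <- function(sample_ids, n_rep = 2500L, seed) {
  n <- length(sample_ids)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (missing(seed)) stop("seed is required for reproducibility",
                          call. = FALSE)
  pool <- rep(sample_ids, times = n_rep)
  perm <- with_local_seed(seed, sample(pool, length(pool), replace = FALSE))
  split(perm, rep(seq_len(n_rep), each = n))
}

# evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic per-purpose stream derived from a study-level seed
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  raw <- utils::head(charToRaw(digest_string(key)), 4)
  val <- sum(as.integer(raw) * 256^(0:3)) %% .Machine$integer.max
  as.integer(val)
}

# small string hash (FNV-1a), avoids an external digest dependency
digest_string <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  paste0(format(h, scientific = FALSE), "x", nchar(s))
}

#' Bootstrap distributions of mechanostat parameters
#'
#' For each balanced-bootstrap replicate the group curve is rebuilt from
#' the resampled samples' surface tables (including the shared cap and the
#' at-least-`min_samples` bin filter) and refitted; each parameter's
#' replicate values, median and IQR are collected.
#'
#' @param tables named list of per-sample surface tables (>= 3 samples).
#' @param fit_kind `"piecewise"` or `"hyperbola"`.
#' @param voxel_size,interval_days,min_samples,n_bins passed to
#'   [group_average_curve()].
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @param max_failure_rate abort when more than this fraction of replicate
#'   fits fail (default 0.2).
#' @return an object of class `bootstrap_distributions`: list with
#'   `replicates` (tibble: `replicate`, `term`, `estimate`), `summary`
#'   (tibble: `term`, `median`, `q25`, `q75`, `n_ok`), `n_failed`, `seed`.
#' @export
bootstrap_parameter_distributions <- function(tables,
                                              fit_kind = c("piecewise",
                                                           "hyperbola"),
                                              voxel_size, interval_days,
                                              n_rep = 2500L, seed,
                                              min_samples = 3L,
                                              n_bins = 100L,
                                              max_failure_rate = 0.2) {
  fit_kind <- match.arg(fit_kind)
  if (length(tables) < 3L) {
    stop("need a group of >= 3 samples", call. = FALSE)
  }
  if (is.null(names(tables))) names(tables) <- as.character(seq_along(tables))
  reps <- balanced_bootstrap_replicates(names(tables), n_rep = n_rep,
                                        seed = seed)
  fitter <- if (fit_kind == "piecewise") fit_piecewise else fit_hyperbola
  rows <- vector("list", length(reps))
  n_failed <- 0L
  for (r in seq_along(reps)) {
    res <- tryCatch({
      curve <- group_average_curve(tables[reps[[r]]],
                                   voxel_size = voxel_size,
                                   interval_days = interval_days,
                                   min_samples = min_samples,
                                   n_bins = n_bins)
      fit <- fitter(curve)
      tibble::tibble(replicate = r, term = names(fit$parameters),
                     estimate = unname(fit$parameters))
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[r]] <- res
  }
  if (n_failed > max_failure_rate * n_rep) {
    stop(sprintf("bootstrap aborted: %d of %d replicate fits failed",
                 n_failed, n_rep), call. = FALSE)
  }
  replicates <- dplyr::bind_rows(rows)
  summary <- replicates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median = stats::median(.data$estimate),
      q25 = stats::quantile(.data$estimate, 0.25, names = FALSE),
      q75 = stats::quantile(.data$estimate, 0.75, names = FALSE),
      n_ok = dplyr::n(), .groups = "drop")
  structure(list(replicates = replicates, summary = summary,
                 n_failed = n_failed, seed = seed, fit_kind = fit_kind),
            class = "bootstrap_distributions")
}

#' @export
print.bootstrap_distributions <- function(x, ...) {
  cat(sprintf("<balanced bootstrap: %s fits> %d failed replicate(s)\n",
              x$fit_kind, x$n_failed))
  print(x$summary)
  invisible(x)
}

#' Logarithmic regression of a parameter on loading frequency
#'
#' Ordinary least squares of `y = y0 + a ln(f)`; only cyclic groups
#' (`f > 0` Hz) can enter. Fit quality is the pseudo-R^2
#' `1 - SS_res / SS_tot`.
#'
#' @param frequencies loading frequencies in Hz (>= 2 distinct, all > 0).
#' @param values parameter values (e.g. bootstrap medians), same length.
#' @return an object of class `log_frequency_fit` with `y0`, `a`,
#'   `pseudo_r2`, `frequencies`, `values`, `fitted`.
#' @export
log_frequency_fit <- function(frequencies, values) {
  if (length(frequencies) != length(values)) {
    stop("frequencies and values differ in length", call. = FALSE)
  }
  if (any(frequencies <= 0)) {
    stop("all frequencies must be > 0 Hz (sham/static groups cannot enter a log fit)",
         call. = FALSE)
  }
  if (length(unique(frequencies)) < 2L) {
    stop("need >= 2 distinct frequencies", call. = FALSE)
  }
  lf <- log(frequencies)
  fit <- stats::lm(values ~ lf)
  fitted <- unname(stats::fitted(fit))
  ss_res <- sum((values - fitted)^2)
  ss_tot <- sum((values - mean(values))^2)
  pseudo_r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(y0 = unname(stats::coef(fit)[1]),
                 a = unname(stats::coef(fit)[2]),
                 pseudo_r2 = pseudo_r2,
                 frequencies = frequencies, values = values,
                 fitted = fitted),
            class = "log_frequency_fit")
}

#' @export
print.log_frequency_fit <- function(x, ...) {
  cat(sprintf("<log-frequency fit> y = %.4g + %.4g ln(f), pseudo-R2 = %.4f\n",
              x$y0, x$a, x$pseudo_r2))
  invisible(x)
}

#' @rdname log_frequency_fit
#' @param x a `log_frequency_fit`.
#' @param ... unused.
#' @method tidy log_frequency_fit
#' @export
tidy.log_frequency_fit <- function(x, ...) {
  tibble::tibble(term = c("y0", "a"), estimate = c(x$y0, x$a))
}

#' @rdname log_frequency_fit
#' @method glance log_frequency_fit
#' @export
glance.log_frequency_fit <- function(x, ...) {
  tibble::tibble(pseudo_r2 = x$pseudo_r2, n = length(x$frequencies))
}

#' Plot a log-frequency fit
#'
#' @param object a `log_frequency_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot log_frequency_fit
#' @export
autoplot.log_frequency_fit <- function(object, ...) {
  df <- tibble::tibble(f = object$frequencies, y = object$values)
  grid <- exp(seq(log(min(df$f)), log(max(df$f)), length.out = 100))
  line <- tibble::tibble(f = grid, y = object$y0 + object$a * log(grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f, y = .data$y)) +
    ggplot2::geom_line(data = line, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "loading frequency (Hz)", y = "parameter value") +
    ggplot2::theme_minimal()
}
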