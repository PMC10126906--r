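#' Conditional-probability curves of (re)modeling events
#'
#' Signal values of all surface voxels are normalized by their 99th
#' percentile (linear-interpolation quantile over the pooled values), binned
#' at 1% of that cap into 100 bins (values above the cap fall into the top
#' bin), and the counts of each event are first normalized by the event's
#' total count to remove the imbalance between formation, quiescence and
#' resorption before conditional probabilities are formed:
#' `p(e | b) = (n_e(b)/N_e) / sum_e'(n_e'(b)/N_e')`. In every populated bin
#' the three probabilities sum to one; bins with no observations are flagged
#' as unpopulated rather than zero-filled.
#'
#' @param table a surface sample table with `event` and `signal` columns
#'   (see [build_surface_table()] and [sample_surface_signal()]).
#' @param n_bins number of bins (default 100, i.e. 1% of the cap each).
#' @return an object of class `cond_prob_curves`: a list with `curves` (a
#'   tibble with `bin`, `bin_center_pct`, per-event counts, normalized
#'   counts and probabilities, `populated`), `totals`, and `cap` (the
#'   99th-percentile signal value).
#' @export
conditional_probabilities <- function(table, n_bins = 100L) {
  if (nrow(table) == 0L) {
    stop("empty surface table", call. = FALSE)
  }
  if (any(is.na(table$signal))) {
    stop("signal column contains NA; run sample_surface_signal() first",
         call. = FALSE)
  }
  events <- c("formation", "quiescence", "resorption")
  totals <- vapply(events, function(e) sum(table$event == e), 0L)
  if (any(totals == 0L)) {
    warning("degenerate table: at least one event class is empty",
            call. = FALSE)
  }
  cap <- stats::quantile(table$signal, 0.99, names = FALSE, type = 7)
  bin <- signal_bin(table$signal, cap, n_bins)
  counts <- matrix(0L, n_bins, 3L, dimnames = list(NULL, events))
  for (e in events) {
    t_e <- tabulate(bin[table$event == e], nbins = n_bins)
    counts[, e] <- t_e
  }
  norm <- sweep(counts, 2, pmax(totals, 1L), "/")
  denom <- rowSums(norm)
  populated <- rowSums(counts) > 0L
  probs <- norm / ifelse(denom > 0, denom, NA_real_)
  curves <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_center_pct = (seq_len(n_bins) - 0.5) * (100 / n_bins),
    n_formation = counts[, 1], n_quiescence = counts[, 2],
    n_resorption = counts[, 3],
    p_formation = probs[, 1], p_quiescence = probs[, 2],
    p_resorption = probs[, 3],
    populated = populated
  )
  structure(list(curves = curves, totals = totals, cap = cap,
                 n_bins = n_bins),
            class = "cond_prob_curves")
}

signal_bin <- function(signal, cap, n_bins) {
  if (any(signal < 0)) {
    stop("signal values must be non-negative", call. = FALSE)
  }
  if (cap <= 0) {
    # degenerate all-zero signal: everything in the first bin
    return(rep(1L, length(signal)))
  }
  b <- floor(signal / cap * n_bins) + 1L
  pmin(pmax(b, 1L), n_bins)
}

#' @export
print.cond_prob_curves <- function(x, ...) {
  cat(sprintf(
    "<conditional probability curves> %d bins (%d populated), cap %.4g\n",
    x$n_bins, sum(x$curves$populated), x$cap))
  cat(sprintf("  totals: formation %d, quiescence %d, resorption %d\n",
              x$totals[1], x$totals[2], x$totals[3]))
  invisible(x)
}

#' Correct classification rate of the ternary event prediction
#'
#' Two thresholds on the normalized signal axis define three intervals
#' (resorption below `t_r`, quiescence between, formation at and above
#' `t_f`). A 3x3 confusion matrix is filled with the sums of each event's
#' conditional probabilities over the bins of each interval, and the CCR is
#' its trace normalized by its total (the number of populated bins).
#' All bin-boundary pairs `t_r <= t_f` are swept exhaustively and the pair
#' maximizing the CCR is returned; ties resolve to the smallest
#' `(t_r, t_f)`. Unpopulated bins are excluded from both the sums and the
#' normalization.
#'
#' @param curves a `cond_prob_curves` object.
#' @return an object of class `ccr_result`: list with `ccr`, `t_r`, `t_f`
#'   (normalized signal, %), and `confusion` (3x3, rows = events, columns =
#'   predicted intervals).
#' @export
compute_ccr <- function(curves) {
  stopifnot(inherits(curves, "cond_prob_curves"))
  cv <- curves$curves[curves$curves$populated, ]
  if (nrow(cv) == 0L) {
    stop("no populated bins", call. = FALSE)
  }
  n_bins <- curves$n_bins
  width <- 100 / n_bins
  P <- cbind(cv$p_resorption, cv$p_quiescence, cv$p_formation)
  # cumulative sums over populated bins, ordered by bin
  cum <- apply(P, 2, cumsum)
  cum <- rbind(0, cum)
  m <- nrow(cv)
  total <- m
  best <- list(ccr = -Inf, i = NA_integer_, j = NA_integer_)
  # thresholds between populated-bin positions: i bins below t_r,
  # j bins below t_f (i <= j)
  for (i in 0:m) {
    res_sum <- cum[i + 1, 1]
    for (j in i:m) {
      qui_sum <- cum[j + 1, 2] - cum[i + 1, 2]
      for_sum <- cum[m + 1, 3] - cum[j + 1, 3]
      trace <- res_sum + qui_sum + for_sum
      if (trace > best$ccr * total + 1e-12) {
        best <- list(ccr = trace / total, i = i, j = j)
      }
    }
  }
  i <- best$i; j <- best$j
  # threshold as the upper boundary of the last bin in the interval (%)
  t_r <- if (i == 0) 0 else cv$bin[i] * width
  t_f <- if (j == 0) 0 else cv$bin[j] * width
  low <- seq_len(m) <= i
  mid <- seq_len(m) > i & seq_len(m) <= j
  high <- seq_len(m) > j
  confusion <- rbind(
    resorption = c(sum(P[low, 1]), sum(P[mid, 1]), sum(P[high, 1])),
    quiescence = c(sum(P[low, 2]), sum(P[mid, 2]), sum(P[high, 2])),
    formation = c(sum(P[low, 3]), sum(P[mid, 3]), sum(P[high, 3]))
  )
  colnames(confusion) <- c("pred_resorption", "pred_quiescence",
                           "pred_formation")
  flagged <- m == 1L
  structure(list(ccr = best$ccr, t_r = t_r, t_f = t_f,
                 confusion = confusion, n_populated = m,
                 degenerate = flagged),
            class = "ccr_result")
}

#' @export
print.ccr_result <- function(x, ...) {
  cat(sprintf("<CCR> %.4f at t_r = %.1f%%, t_f = %.1f%% (%d populated bins)\n",
              x$ccr, x$t_r, x$t_f, x$n_populated))
  invisible(x)
}

#' @rdname compute_ccr
#' @param x a `ccr_result` (for `tidy`) or `cond_prob_curves`.
#' @param ... unused.
#' @method tidy ccr_result
#' @export
tidy.ccr_result <- function(x, ...) {
  tibble::tibble(ccr = x$ccr, t_r = x$t_r, t_f = x$t_f,
                 n_populated = x$n_populated)
}

#' Tidy conditional-probability curves to a long tibble
#'
#' @param x a `cond_prob_curves` object.
#' @param ... unused.
#' @return a tibble with one row per (bin, event).
#' @method tidy cond_prob_curves
#' @export
tidy.cond_prob_curves <- function(x, ...) {
  cv <- x$curves
  tidyr::pivot_longer(
    cv[, c("bin", "bin_center_pct", "populated", "p_formation",
           "p_quiescence", "p_resorption")],
    cols = dplyr::starts_with("p_"),
    names_to = "event", names_prefix = "p_", values_to = "probability"
  )
}

#' Plot conditional-probability curves
#'
#' @param object a `cond_prob_curves` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cond_prob_curves
#' @export
autoplot.cond_prob_curves <- function(object, ...) {
  df <- tidy.cond_prob_curves(object)
  df <- df[df$populated, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin_center_pct, y = .data$probability,
    colour = .data$event)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed") +
    ggplot2::labs(x = "normalized mechanical signal (%)",
                  y = "conditional probability") +
    ggplot2::theme_minimal()
}
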