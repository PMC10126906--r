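#' Mechanostat functions
#'
#' Two parametric descriptions of the (re)modeling velocity curve are
#' supported. The piecewise-linear mechanostat clamps two linear branches:
#' `RmV(ms) = clamp(RVM (ms - RT), RSL, 0) + clamp(FVM (ms - FT), 0, FSL)`,
#' i.e. constant `RSL` below `RT + RSL/RVM`, rising through zero on
#' `[RT, FT]` (the adapted window), and saturating at `FSL` above
#' `FT + FSL/FVM`. The hyperbola is `RmV(ms) = FSL - RmVM / (RmT + ms)`,
#' which crosses zero at `RmVM/FSL - RmT` and has no flat adapted window;
#' its resorption saturation level RSL is defined as the value of the
#' function at the minimum observed signal.
#'
#' @param ms mechanical signal values.
#' @param RSL,RVM,RT,FT,FVM,FSL piecewise parameters: saturation levels in
#'   um/day (RSL <= 0 <= FSL), velocity moduli in um/day per signal unit
#'   (> 0), thresholds in signal units with RT <= FT.
#' @param RmVM,RmT hyperbola scale (um/day x signal unit) and threshold
#'   parameter (signal units).
#' @return numeric vector of velocities (um/day).
#' @name mechanostat_functions
NULL

#' @rdname mechanostat_functions
#' @export
piecewise_rmv <- function(ms, RSL, RVM, RT, FT, FVM, FSL) {
  pmin(pmax(RVM * (ms - RT), RSL), 0) + pmin(pmax(FVM * (ms - FT), 0), FSL)
}

#' @rdname mechanostat_functions
#' @export
hyperbola_rmv <- function(ms, FSL, RmVM, RmT) {
  FSL - RmVM / (RmT + ms)
}

#' Fit the piecewise-linear mechanostat to an RmV curve
#'
#' Unweighted least squares over the unmasked bins, by bounded
#' Levenberg-Marquardt with a deterministic multi-start grid over the
#' threshold parameters (to escape the local minima typical of segmented
#' fits). `FT` is parameterized as `RT + dFT` with `dFT >= 0` so the
#' threshold order constraint always holds.
#'
#' @param curve an `rmv_curve`.
#' @param bounds named list overriding the default box constraints
#'   (`RSL` in `[-50, 0]`, `FSL` in `[0, 50]` um/day, moduli positive,
#'   thresholds within the observed signal range).
#' @param n_starts grid resolution for the (RT, FT) multi-start.
#' @param weighted if `TRUE`, weight residuals by per-bin counts (off by
#'   default: each signal bin counts equally).
#' @return an object of class `mechanostat_fit` (kind `"piecewise"`) with
#'   elements `parameters` (RSL, RVM, RT, FT, FVM, FSL), `rmse`, `n_bins`,
#'   and `flags` (e.g. an unidentifiable resorption branch when the curve
#'   never goes negative).
#' @export
fit_piecewise <- function(curve, bounds = list(), n_starts = 6L,
                          weighted = FALSE) {
  dat <- fit_data(curve, min_bins = 6L)
  ms <- dat$ms; y <- dat$y; w <- if (weighted) dat$w else rep(1, length(y))
  rng <- range(ms)
  span <- diff(rng)
  b <- utils::modifyList(list(
    RSL = c(-50, 0), FSL = c(0, 50),
    RVM = c(1e-8, Inf), FVM = c(1e-8, Inf),
    RT = rng, dFT = c(0, span)
  ), bounds)

  flags <- character(0)
  if (all(y >= 0)) flags <- c(flags, "resorption_branch_unidentifiable")
  if (all(y <= 0)) flags <- c(flags, "formation_branch_unidentifiable")

  model <- function(p) {
    piecewise_rmv(ms, p[["RSL"]], p[["RVM"]], p[["RT"]],
                  p[["RT"]] + p[["dFT"]], p[["FVM"]], p[["FSL"]])
  }
  resid_fn <- function(p) sqrt(w) * (model(p) - y)

  slope0 <- max(abs(diff(range(y))) / span, 1e-6)
  rt_grid <- seq(rng[1] + 0.05 * span, rng[2] - 0.05 * span,
                 length.out = n_starts)
  dft_grid <- span * c(0.02, 0.15, 0.4)
  starts <- expand.grid(RT = rt_grid, dFT = dft_grid)

  lower <- c(RSL = b$RSL[1], RVM = b$RVM[1], RT = b$RT[1], dFT = b$dFT[1],
             FVM = b$FVM[1], FSL = b$FSL[1])
  upper <- c(RSL = b$RSL[2], RVM = b$RVM[2], RT = b$RT[2], dFT = b$dFT[2],
             FVM = b$FVM[2], FSL = b$FSL[2])
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- c(RSL = max(min(y), b$RSL[1]), RVM = slope0,
            RT = starts$RT[s], dFT = starts$dFT[s],
            FVM = slope0, FSL = min(max(y), b$FSL[2]))
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse - 1e-14) {
      best <- list(par = fit$par, sse = sse)
    }
  }
  if (is.null(best)) {
    stop("piecewise fit failed to converge from any start", call. = FALSE)
  }
  p <- best$par
  params <- c(RSL = unname(p[["RSL"]]), RVM = unname(p[["RVM"]]),
              RT = unname(p[["RT"]]), FT = unname(p[["RT"]] + p[["dFT"]]),
              FVM = unname(p[["FVM"]]), FSL = unname(p[["FSL"]]))
  fitted <- piecewise_rmv(ms, params["RSL"], params["RVM"], params["RT"],
                          params["FT"], params["FVM"], params["FSL"])
  new_mechanostat_fit("piecewise", params, y, fitted, flags,
                      signal_range = rng)
}

#' Fit the hyperbola mechanostat to an RmV curve
#'
#' Bounded Levenberg-Marquardt with a deterministic multi-start over `RmT`.
#' The pole `-RmT` is constrained to lie below the observed signal range.
#' `RSL` is computed post hoc as the fitted function's value at the minimum
#' observed signal, and the zero crossing `RmVM/FSL - RmT` is reported
#' alongside the parameters.
#'
#' @inheritParams fit_piecewise
#' @return a `mechanostat_fit` (kind `"hyperbola"`) with parameters `FSL`,
#'   `RmVM`, `RmT`, derived `RSL` and `zero_crossing`, plus `rmse`.
#' @export
fit_hyperbola <- function(curve, bounds = list(), n_starts = 8L,
                          weighted = FALSE) {
  dat <- fit_data(curve, min_bins = 3L)
  ms <- dat$ms; y <- dat$y; w <- if (weighted) dat$w else rep(1, length(y))
  rng <- range(ms)
  span <- max(diff(rng), rng[2], 1e-8)
  b <- utils::modifyList(list(
    FSL = c(0, 50), RmVM = c(0, Inf),
    RmT = c(-rng[1] + 1e-6 * span, Inf)
  ), bounds)

  resid_fn <- function(p) {
    sqrt(w) * (hyperbola_rmv(ms, p[["FSL"]], p[["RmVM"]], p[["RmT"]]) - y)
  }
  lower <- c(FSL = b$FSL[1], RmVM = b$RmVM[1], RmT = b$RmT[1])
  upper <- c(FSL = b$FSL[2], RmVM = b$RmVM[2], RmT = b$RmT[2])
  rmt_grid <- span * c(0.05, 0.15, 0.3, 0.6, 1, 2, 5, 10)[seq_len(n_starts)]
  best <- NULL
  for (rmt0 in rmt_grid) {
    fsl0 <- max(y)
    rmvm0 <- max((fsl0 - min(y)) * (rmt0 + rng[1]), 1e-3)
    p0 <- pmin(pmax(c(FSL = fsl0, RmVM = rmvm0, RmT = rmt0), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$par[["RmT"]] + rng[1] <= 0) next   # pole inside data range
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse - 1e-14) {
      best <- list(par = fit$par, sse = sse)
    }
  }
  if (is.null(best)) {
    stop("hyperbola fit failed to converge from any start", call. = FALSE)
  }
  p <- best$par
  params <- c(FSL = unname(p[["FSL"]]), RmVM = unname(p[["RmVM"]]),
              RmT = unname(p[["RmT"]]))
  params["RSL"] <- hyperbola_rmv(rng[1], params["FSL"], params["RmVM"],
                                 params["RmT"])
  params["zero_crossing"] <- if (params["FSL"] > 0) {
    params["RmVM"] / params["FSL"] - params["RmT"]
  } else {
    NA_real_
  }
  fitted <- hyperbola_rmv(ms, params["FSL"], params["RmVM"], params["RmT"])
  new_mechanostat_fit("hyperbola", params, y, fitted, character(0),
                      signal_range = rng)
}

fit_data <- function(curve, min_bins) {
  stopifnot(inherits(curve, "rmv_curve"))
  ok <- !is.na(curve$rmv) & curve$counts > 0
  if (sum(ok) < min_bins) {
    stop(sprintf("need >= %d unmasked bins, have %d", min_bins, sum(ok)),
         call. = FALSE)
  }
  list(ms = curve$signal[ok], y = curve$rmv[ok], w = curve$counts[ok])
}

new_mechanostat_fit <- function(kind, parameters, y, fitted, flags,
                                signal_range) {
  structure(
    list(kind = kind, parameters = parameters,
         rmse = sqrt(mean((fitted - y)^2)), n_bins = length(y),
         flags = flags, signal_range = signal_range),
    class = "mechanostat_fit")
}

#' Evaluate a mechanostat fit at new signal values
#'
#' @param fit a `mechanostat_fit`.
#' @param ms mechanical signal values.
#' @return velocities (um/day).
#' @export
predict_mechanostat <- function(fit, ms) {
  stopifnot(inherits(fit, "mechanostat_fit"))
  p <- fit$parameters
  if (fit$kind == "piecewise") {
    piecewise_rmv(ms, p["RSL"], p["RVM"], p["RT"], p["FT"], p["FVM"],
                  p["FSL"])
  } else {
    hyperbola_rmv(ms, p["FSL"], p["RmVM"], p["RmT"])
  }
}

#' @export
print.mechanostat_fit <- function(x, ...) {
  cat(sprintf("<mechanostat fit: %s> rmse %.4g um/day over %d bins\n",
              x$kind, x$rmse, x$n_bins))
  print(round(x$parameters, 4))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Broom-style accessors for mechanostat fits
#'
#' @param x a `mechanostat_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per parameter; `glance()`: one-row model
#'   summary with `kind`, `rmse`, `n_bins`.
#' @method tidy mechanostat_fit
#' @export
tidy.mechanostat_fit <- function(x, ...) {
  tibble::tibble(term = names(x$parameters),
                 estimate = unname(x$parameters))
}

#' @rdname tidy.mechanostat_fit
#' @method glance mechanostat_fit
#' @export
glance.mechanostat_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, rmse = x$rmse, n_bins = x$n_bins,
                 flags = paste(x$flags, collapse = ";"))
}
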