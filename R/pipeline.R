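#' Pipeline orchestration
#'
#' [run_pair()] runs the complete per-sample analysis for one registered
#' baseline/follow-up pair; [run_study()] maps it over a study manifest,
#' builds group-average curves and fits, balanced-bootstrap parameter
#' distributions, and the log-frequency regression across cyclic groups.
#'
#' @name pipeline
NULL

#' Analysis configuration for one image pair
#'
#' @param signal mechanical signal descriptor: `"effective_strain"`
#'   (microstrain, bone side), `"sed"` (MPa, bone side) or
#'   `"grad_sed_norm"` (MPa/um, marrow side).
#' @param material a [material_map()] (used to convert SED to effective
#'   strain; homogeneous mode uses `E_bone` on the bone side).
#' @param interval_days scan interval in days.
#' @param F_fe,F_target optional forces (N) for linear rescaling of the FE
#'   solution to the in-vivo load (e.g. `F_target = 8` for loaded groups,
#'   `4` for sham); omit both to skip rescaling.
#' @param n_bins number of signal bins.
#' @param min_samples group-curve bin filter (samples per bin).
#' @return a `pair_config` list.
#' @export
pair_config <- function(signal = c("effective_strain", "sed",
                                   "grad_sed_norm"),
                        material = material_map(), interval_days = 7,
                        F_fe = NULL, F_target = NULL, n_bins = 100L,
                        min_samples = 3L) {
  signal <- match.arg(signal)
  structure(list(signal = signal, material = material,
                 interval_days = interval_days, F_fe = F_fe,
                 F_target = F_target, n_bins = n_bins,
                 min_samples = min_samples),
            class = "pair_config")
}

signal_field_from_sed <- function(sed, bone, config) {
  field <- switch(config$signal,
    sed = signal_field(sed, "sed"),
    grad_sed_norm = sed_gradient_norm(sed),
    effective_strain = {
      E_field <- modulus_from_binary(bone, config$material)
      effective_strain_field(sed, E_field)
    })
  if (!is.null(config$F_fe) && !is.null(config$F_target)) {
    field <- rescale_to_force(field, config$F_fe, config$F_target)
  }
  field
}

#' Run the full analysis for one baseline/follow-up pair
#'
#' @param baseline,followup registered [binary_volume()]s.
#' @param mask trabecular compartment [binary_volume()].
#' @param sed baseline SED [scalar_volume()] (MPa) from FE analysis, or a
#'   ready-made `signal_field` (then `config$signal` is ignored).
#' @param config a [pair_config()].
#' @return list of class `pair_result`: `table` (surface sample table),
#'   `cond_prob` ([conditional_probabilities()]), `ccr` ([compute_ccr()]),
#'   `curve` ([compute_rmv_curve()]), `fit_piecewise`, `fit_hyperbola`
#'   (either may be `NULL` with the failure recorded in `qc`), `qc`.
#' @export
run_pair <- function(baseline, followup, mask, sed,
                     config = pair_config()) {
  table <- build_surface_table(baseline, followup, mask)
  bone <- binary_volume(baseline$data * mask$data, baseline$voxel_size)
  field <- if (inherits(sed, "signal_field")) {
    sed
  } else {
    signal_field_from_sed(sed, bone, config)
  }
  table <- sample_surface_signal(table, field, bone)
  cond_prob <- conditional_probabilities(table, n_bins = config$n_bins)
  ccr <- compute_ccr(cond_prob)
  curve <- compute_rmv_curve(table, voxel_size = baseline$voxel_size,
                             interval_days = config$interval_days,
                             n_bins = config$n_bins)
  qc <- attr(table, "qc")
  fit_pw <- tryCatch(fit_piecewise(curve), error = function(e) {
    qc$piecewise_error <<- conditionMessage(e); NULL
  })
  fit_hy <- tryCatch(fit_hyperbola(curve), error = function(e) {
    qc$hyperbola_error <<- conditionMessage(e); NULL
  })
  structure(list(table = table, cond_prob = cond_prob, ccr = ccr,
                 curve = curve, fit_piecewise = fit_pw,
                 fit_hyperbola = fit_hy, qc = qc, config = config),
            class = "pair_result")
}

#' Run a whole study from a manifest
#'
#' The manifest is a tibble with one row per sample: `sample_id`, `group`,
#' `frequency_hz` (`NA` for sham/static groups) and either list-columns
#' `baseline`, `followup`, `mask`, `sed` holding volume objects, or path
#' columns `baseline_path`, `followup_path`, `mask_path`, `sed_path` read
#' with [read_volume()].
#'
#' @param manifest the study manifest tibble.
#' @param config a [pair_config()].
#' @param n_rep balanced-bootstrap replicates per group (default 2500).
#' @param seed study-level seed; per-group streams are derived from it.
#' @param bootstrap_kind fit refitted per replicate (`"piecewise"` or
#'   `"hyperbola"`).
#' @param log_fit_terms parameters regressed on `ln(frequency)` across the
#'   cyclic groups (defaults: FSL, RT, FT for piecewise fits).
#' @return list of class `study_result`: `pairs` (per-sample
#'   `pair_result`s), `groups` (per-group curve, fits and bootstrap), and
#'   `log_fits` (per term, or `NULL` if fewer than two cyclic groups).
#' @export
run_study <- function(manifest, config = pair_config(), n_rep = 2500L,
                      seed = 1L,
                      bootstrap_kind = c("piecewise", "hyperbola"),
                      log_fit_terms = NULL) {
  bootstrap_kind <- match.arg(bootstrap_kind)
  log_fit_terms <- log_fit_terms %||%
    (if (bootstrap_kind == "piecewise") c("FSL", "RT", "FT")
     else c("FSL", "RmT"))
  needed <- c("sample_id", "group")
  if (!all(needed %in% names(manifest))) {
    stop("manifest needs sample_id and group columns", call. = FALSE)
  }
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    vols <- manifest_volumes(row)
    out <- run_pair(vols$baseline, vols$followup, vols$mask, vols$sed,
                    config = config)
    out$sample_id <- row$sample_id
    out$group <- row$group
    out
  })
  names(pairs) <- manifest$sample_id

  groups <- list()
  for (g in unique(manifest$group)) {
    rows <- which(manifest$group == g)
    tables <- lapply(pairs[rows], function(p) p$table)
    names(tables) <- manifest$sample_id[rows]
    vs <- pairs[[rows[1]]]$table |> attr("voxel_size")
    if (length(rows) < config$min_samples) {
      warning(sprintf("group '%s' below minimum size; skipped", g),
              call. = FALSE)
      next
    }
    curve <- group_average_curve(tables, voxel_size = vs,
                                 interval_days = config$interval_days,
                                 min_samples = config$min_samples,
                                 n_bins = config$n_bins)
    fit_pw <- tryCatch(fit_piecewise(curve), error = function(e) NULL)
    fit_hy <- tryCatch(fit_hyperbola(curve), error = function(e) NULL)
    boot <- bootstrap_parameter_distributions(
      tables, fit_kind = bootstrap_kind, voxel_size = vs,
      interval_days = config$interval_days, n_rep = n_rep,
      seed = derive_seed(seed, "bootstrap", g),
      min_samples = config$min_samples, n_bins = config$n_bins)
    freq <- manifest$frequency_hz[rows[1]] %||% NA_real_
    groups[[g]] <- list(group = g, frequency_hz = freq, curve = curve,
                        fit_piecewise = fit_pw, fit_hyperbola = fit_hy,
                        bootstrap = boot)
  }

  log_fits <- NULL
  freqs <- vapply(groups, function(g) as.numeric(g$frequency_hz %||% NA),
                  0)
  cyclic <- which(!is.na(freqs) & freqs > 0)
  if (length(cyclic) >= 2L) {
    log_fits <- list()
    for (term in log_fit_terms) {
      med <- vapply(groups[cyclic], function(g) {
        s <- g$bootstrap$summary
        m <- s$median[s$term == term]
        if (length(m)) m else NA_real_
      }, 0)
      ok <- !is.na(med)
      if (sum(ok) >= 2L) {
        log_fits[[term]] <- log_frequency_fit(freqs[cyclic][ok], med[ok])
      }
    }
  }
  structure(list(pairs = pairs, groups = groups, log_fits = log_fits,
                 config = config, seed = seed),
            class = "study_result")
}

manifest_volumes <- function(row) {
  get_vol <- function(obj_col, path_col, binary, required = TRUE) {
    if (obj_col %in% names(row) && !is.null(row[[obj_col]][[1]])) {
      return(row[[obj_col]][[1]])
    }
    if (path_col %in% names(row) && !is.na(row[[path_col]])) {
      return(read_volume(row[[path_col]], binary = binary))
    }
    if (required) {
      stop(sprintf(
        "manifest sample '%s': missing %s (no volume object and no path)",
        row$sample_id, obj_col), call. = FALSE)
    }
    NULL
  }
  list(baseline = get_vol("baseline", "baseline_path", TRUE),
       followup = get_vol("followup", "followup_path", TRUE),
       mask = get_vol("mask", "mask_path", TRUE),
       sed = get_vol("sed", "sed_path", FALSE) %||%
         stop("manifest: missing SED field (column 'sed' or 'sed_path')",
              call. = FALSE))
}

#' Write the per-sample outputs of a pair analysis
#'
#' Serializes the surface table and RmV curve as CSV and the probability
#' curves, CCR, fits and QC counters as JSON.
#'
#' @param result a `pair_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pair_result <- function(result, dir) {
  stopifnot(inherits(result, "pair_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tibble::as_tibble(result$table),
                   file.path(dir, "surface_table.csv"), row.names = FALSE)
  utils::write.csv(tibble::as_tibble(result$curve),
                   file.path(dir, "rmv_curve.csv"), row.names = FALSE)
  utils::write.csv(result$cond_prob$curves,
                   file.path(dir, "conditional_probabilities.csv"),
                   row.names = FALSE)
  report <- list(
    ccr = as.list(tidy.ccr_result(result$ccr)),
    cap = result$cond_prob$cap,
    fits = list(
      piecewise = if (!is.null(result$fit_piecewise)) {
        as.list(result$fit_piecewise$parameters)
      },
      hyperbola = if (!is.null(result$fit_hyperbola)) {
        as.list(result$fit_hyperbola$parameters)
      }
    ),
    rmse = list(
      piecewise = result$fit_piecewise$rmse %||% NA,
      hyperbola = result$fit_hyperbola$rmse %||% NA
    ),
    qc = result$qc
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
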