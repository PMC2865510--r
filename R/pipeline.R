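#' Assemble (or read) a pipeline configuration
#'
#' A plain list validated against the fields the pipeline understands.
#' `K` may be `"auto"` or a named list/vector of three values.
#'
#' @param reporter_csv Path to the reporter table CSV (default: the
#'   packaged library, see [hsc_reporter_library()]).
#' @param K `"auto"` or named chromatin constants.
#' @param fold_notch,fold_bmp4 Cofactor calibration folds.
#' @param half_lives Protein half-lives in hours (Scl, Gata2, Fli1).
#' @param time_unit `"mean_lifetime"` or `"half_life"`.
#' @param out_dir Output directory for pipeline products.
#' @param seed Integer seed (used only by synthetic generation).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reporter_csv = NULL, K = "auto",
                            fold_notch = 3.5, fold_bmp4 = 4,
                            half_lives = c(8, 1 / 6, 2),
                            time_unit = "mean_lifetime",
                            out_dir = tempfile("triadswitch-"),
                            seed = 1L) {
  cfg <- list(reporter_csv = reporter_csv, K = K, fold_notch = fold_notch,
              fold_bmp4 = fold_bmp4, half_lives = half_lives,
              time_unit = match.arg(time_unit,
                                    c("mean_lifetime", "half_life")),
              out_dir = out_dir, seed = as.integer(seed))
  if (!is.numeric(cfg$half_lives) || length(cfg$half_lives) != 3L ||
      any(cfg$half_lives <= 0)) {
    abort("`half_lives` must be three positive numbers.")
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML or JSON
#'
#' Named vectors are serialized as maps (names preserved) and numbers at
#' full precision, so [read_pipeline_config()] restores the config.
#'
#' @param config A [pipeline_config()].
#' @param path Output path; the extension picks the format.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  payload <- unclass(config)
  if (!identical(payload$K, "auto")) payload$K <- as.list(payload$K)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path, precision = 15)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  raw$half_lives <- as.numeric(unlist(raw$half_lives %||% c(8, 1 / 6, 2)))
  if (!is.null(raw$K) && !identical(raw$K, "auto")) {
    raw$K <- unlist(raw$K)
  }
  do.call(pipeline_config, raw)
}

config_table <- function(cfg) {
  if (is.null(cfg$reporter_csv)) hsc_reporter_library() else
    read_reporter_csv(cfg$reporter_csv)
}

write_provenance <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- cfg
  class(keep) <- NULL
  jsonlite::write_json(keep, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Fit stage of the pipeline
#'
#' Reads the reporter table, chooses/validates chromatin constants, fits
#' all free energies exactly, calibrates the omegas, and writes the
#' fitted model config plus a fit report (feasibility bounds, chosen K,
#' per-construct round-trip residuals) into the output directory.
#' Infeasibility (e.g. `K` at or below a measured fold value) surfaces
#' as a structured `triadswitch_infeasible` error naming the bound.
#'
#' @param config A [pipeline_config()].
#' @return The fitted [triad_params][triad_parameters()], invisibly; the
#'   fit report as attribute `"report"`.
#' @export
pipeline_fit <- function(config) {
  tb <- config_table(config)
  params <- build_triad(tb, K = config$K, fold_notch = config$fold_notch,
                        fold_bmp4 = config$fold_bmp4,
                        half_lives = config$half_lives,
                        time_unit = config$time_unit)
  # round-trip residuals over every construct used by the fit
  resid <- purrr::map_dfr(names(.enhancer_keys), function(key) {
    m <- params$models[[key]]
    purrr::map_dfr(library_constructs(key), function(cs) {
      dm <- delete_sites(m, setdiff(enhancer_sites(key), cs$intact))
      pred <- fold_enhancement(dm, triad_state())
      obs <- lookup_fold(prepare_table(tb, key), cs$intact, m$name)
      tibble(enhancer = m$name, construct = cs$construct,
             observed = obs, predicted = pred,
             rel_residual = abs(pred - obs) / obs)
    })
  })
  bounds <- purrr::map_dbl(names(.enhancer_keys),
                           ~ feasibility_bound(prepare_table(tb, .x)))
  report <- list(
    K = purrr::map_dbl(params$models, "K"),
    feasibility_bounds = setNames(bounds, names(.enhancer_keys)),
    max_rel_residual = max(resid$rel_residual),
    residuals = resid
  )
  write_provenance(config)
  write_enhancer_config(params$models,
                        file.path(config$out_dir, "fitted_models.json"))
  rj <- report
  rj$residuals <- as.data.frame(resid)
  jsonlite::write_json(rj, file.path(config$out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  attr(params, "report") <- report
  invisible(params)
}

#' Analysis stage of the pipeline
#'
#' Runs one of the deterministic analyses on fitted parameters and writes
#' tidy CSV/JSON outputs into the config's output directory:
#' * `"steady"` — zero-signal steady states (`steady_states.csv`).
#' * `"dose"` — response curve on `axis` with classification and
#'   thresholds (`dose_<axis>.csv`, `dose_<axis>.json`).
#' * `"pulse"` — minimum-pulse-duration filter curve on `axis`
#'   (`pulse_<axis>.csv`).
#' * `"mutants"` — classification of the 10 site-deletion designs plus 3
#'   knockouts and 3 heterozygotes (`mutants.csv`).
#'
#' @param config A [pipeline_config()].
#' @param task One of `"steady"`, `"dose"`, `"pulse"`, `"mutants"`.
#' @param params Fitted parameters (from [pipeline_fit()]); refit from
#'   the config if missing.
#' @param axis Signal axis for `dose`/`pulse`.
#' @param amplitudes Amplitude grid for `pulse` (default: 4 log-spaced
#'   multiples of 10 above the static threshold).
#' @return The computed object, invisibly.
#' @export
pipeline_analyze <- function(config, task = c("steady", "dose", "pulse",
                                              "mutants"),
                             params = NULL, axis = "notch",
                             amplitudes = NULL) {
  task <- match.arg(task)
  params <- params %||% pipeline_fit(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(task,
    steady = {
      ss <- find_steady_states(params)
      utils::write.csv(as.data.frame(ss),
                       file.path(config$out_dir, "steady_states.csv"),
                       row.names = FALSE)
      ss
    },
    dose = {
      rc <- trace_response(params, axis)
      utils::write.csv(as.data.frame(tidy(rc)),
                       file.path(config$out_dir,
                                 paste0("dose_", axis, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(axis = rc$axis, classification = rc$classification,
             thresholds = rc$thresholds),
        file.path(config$out_dir, paste0("dose_", axis, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      rc
    },
    pulse = {
      if (is.null(amplitudes)) {
        thr <- static_threshold(params, axis)
        amplitudes <- if (axis == "eta") 10^seq(1, 3, length.out = 4) else
          thr * 10^seq(0.5, 3, length.out = 4)
      }
      fc <- filter_curve(params, axis, amplitudes)
      utils::write.csv(as.data.frame(fc),
                       file.path(config$out_dir,
                                 paste0("pulse_", axis, ".csv")),
                       row.names = FALSE)
      fc
    },
    mutants = {
      designs <- c(enumerate_mutant_designs()$design,
                   "ko:Scl", "ko:Gata2", "ko:Fli1",
                   "het:Scl", "het:Gata2", "het:Fli1")
      res <- purrr::map_dfr(designs, function(d) {
        p <- make_design(params, d)
        rc <- trace_response(p, "notch",
                             grid = c(0, 10^seq(-2, 3, length.out = 11)))
        ss0 <- find_steady_states(p)
        st0 <- dplyr::filter(ss0, .data$stable)
        tibble(design = d, classification = rc$classification,
               n_stable_zero_signal = nrow(st0),
               x_g_top = max(st0$x_g))
      })
      utils::write.csv(as.data.frame(res),
                       file.path(config$out_dir, "mutants.csv"),
                       row.names = FALSE)
      res
    }
  )
  invisible(out)
}
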