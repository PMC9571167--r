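#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default. Any subset can
#' be overridden; unknown keys are rejected.
#'
#' @param ... Named overrides among `ao_profile`, `ao_params`,
#'   `force_floor`, `warmup_cycles`, `ari_threshold`, `ppd_threshold`,
#'   `angtangent_cutoff`, `ang_mode`, `literal_area`, `literal_cv`,
#'   `heel_threshold_frac`, `heel_refractory`.
#' @return List of class `gait_config`.
#' @export
gait_config <- function(...) {
  cfg <- list(
    ao_profile = NULL,        # NULL = follow the trial's group tag
    ao_params = NULL,         # full ao_params() overrides everything
    force_floor = NULL,
    warmup_cycles = 2L,
    ari_threshold = 10,
    ppd_threshold = 10,
    angtangent_cutoff = 0.155,
    ang_mode = "as-printed",
    literal_area = FALSE,
    literal_cv = FALSE,
    heel_threshold_frac = 0.1,
    heel_refractory = 0.3
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
                         class = "gaitpolar_format_error")
  cfg[names(dots)] <- dots
  structure(cfg, class = "gait_config")
}

#' Analyse one GRF trial end to end
#'
#' Runs the full pipeline — COPx extraction, oscillator phase estimation,
#' cycle statistics, polar gaitogram, area/tangent indices, disorder
#' classification, heel-strike detection, PCI and PPD — and assembles a
#' one-row report. Deterministic given the trial and configuration.
#'
#' The oscillator gain profile defaults to the trial's group tag (`"stroke"`
#' uses the slow-adaptation preset, anything else the healthy preset) unless
#' overridden in the config.
#'
#' @param trial A [grf_trial()] (or the list returned by
#'   [generate_trial()]).
#' @param layout A [sensor_layout()].
#' @param config A [gait_config()].
#' @return One-row tibble of class `gait_report` with subject metadata,
#'   cycle-phase statistics, all gaitogram indices, `verdict`,
#'   `affected_side`, `ppd`, `pci` (and components), plus attributes
#'   `config`, `gaitogram`, `phase`, `cop` for inspection and plotting.
#' @examples
#' tr <- generate_trial(gait_template(n_strides = 12, seed = 7))$trial
#' rep <- analyze_trial(tr)
#' rep[, c("ARI", "verdict", "ppd", "pci")]
#' @export
analyze_trial <- function(trial, layout = default_sensor_layout(), config = gait_config()) {
  if (is.list(trial) && !inherits(trial, "grf_trial") && !is.null(trial$trial)) {
    trial <- trial$trial
  }
  stopifnot(inherits(trial, "grf_trial"), inherits(config, "gait_config"))
  group <- attr(trial, "group") %||% "unknown"
  profile <- config$ao_profile %||% (if (identical(group, "stroke")) "stroke" else "healthy")
  params <- config$ao_params %||% ao_params(profile = profile)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e),
                   " (check the input signal and configuration)"),
            class = "gaitpolar_stage_error", parent = e)
    })
  }
  cop <- stage("cop", compute_copx(trial, layout, force_floor = config$force_floor))
  phase <- stage("phase", estimate_phase(cop, params))
  cyc <- stage("cycle_stats", cycle_phase_stats(phase))
  gg <- stage("gaitogram", build_gaitogram(phase, cop, warmup_cycles = config$warmup_cycles))
  idx <- stage("indices", gaitogram_indices(gg, phase, cop, mode = config$ang_mode,
                                            literal_area = config$literal_area))
  cls <- stage("classify", classify_disorder(idx, ari_threshold = config$ari_threshold))
  strikes <- stage("heel_strikes",
                   detect_heel_strikes(trial, layout,
                                       threshold_frac = config$heel_threshold_frac,
                                       refractory = config$heel_refractory))
  pci <- stage("pci", compute_pci(strikes, literal_cv = config$literal_cv))
  ppd <- stage("ppd", compute_ppd(trial))
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = attr(trial, "subject_id"),
      group = group,
      ao_profile = params$profile,
      phase_span_mean = cyc$mean,
      phase_span_sd = cyc$sd,
      phase_deficit = cyc$deficit
    ),
    tibble::as_tibble(idx),
    cls[c("verdict", "affected_side", "unaffected_side")],
    tibble::as_tibble(ppd)[c("ppd", "grf_sum_R", "grf_sum_L")],
    tibble::as_tibble(pci)[c("pci", "p_phi_abs", "phi_cv", "n_strides")]
  )
  structure(out,
            class = c("gait_report", class(tibble::tibble())),
            config = config, gaitogram = gg, phase = phase, cop = cop,
            heel_strikes = strikes)
}

#' Analyse a cohort and compare groups
#'
#' Maps [analyze_trial()] over a cohort tibble (as produced by
#' [generate_cohort()]) and hands the per-subject indices to
#' [compare_groups()].
#'
#' @param cohort Tibble with `subject_id`, `group`, `trial` list-column.
#' @param layout,config Passed to [analyze_trial()].
#' @return List with `reports` (per-subject index tibble) and `comparison`
#'   (a `gait_group_comparison`).
#' @export
analyze_cohort <- function(cohort, layout = default_sensor_layout(), config = gait_config()) {
  reports <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    r <- analyze_trial(cohort$trial[[i]], layout = layout, config = config)
    tibble::as_tibble(r)
  })
  cmp <- compare_groups(reports,
                        ari_threshold = config$ari_threshold,
                        ppd_threshold = config$ppd_threshold,
                        angtangent_cutoff = config$angtangent_cutoff)
  list(reports = reports, comparison = cmp)
}

#' Write a gait report as JSON
#'
#' Serialises the report row plus the configuration echo; numbers keep full
#' precision so re-serialisation is byte-stable.
#'
#' @param report A `gait_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "gait_report"))
  cfg <- attr(report, "config")
  payload <- c(as.list(tibble::as_tibble(report)),
               list(config = unclass(cfg)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
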