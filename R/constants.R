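#' Energy and algorithm constants
#'
#' Central configuration object holding every physiological constant used by
#' the package: the oxygen-to-energy conversion, Weir coefficients, the MET
#' bridge, the blood-lactate oxygen equivalent, per-phase durations,
#' accelerometer cut-points and regression coefficients, non-wear and
#' wear-validity rules, Atwater factors and the isocaloric prescription
#' bands.  Reports produced by [run_pipeline()] embed this object verbatim so
#' every number in a report is traceable to the constants that produced it.
#'
#' Defaults:
#' * `kcal_per_litre_o2 = 5.05` (21.14 kJ) per litre of oxygen.
#' * Weir coefficients 3.941 and 1.106 kcal per litre of VO2 and VCO2
#'   (classic 1949 form), times 1440 min/day for a 24-h RMR.
#' * 1 MET = 3.5 mL O2 per kg per minute.
#' * `lactate_o2_equiv = 3.0` mL O2 per kg per mM lactate accumulation
#'   (di Prampero convention).
#' * `metabolic_duration_by_phase = c(18, 30, 36, 36)` min: the durations
#'   over which per-session METs, MET-hours and kcal/min are expressed.
#'   `circuit_duration_by_phase = c(20, 33, 36, 36)` (rounds x exercises x
#'   1 min) is retained as a selectable alternative, and
#'   `session_duration_by_phase = c(23, 38, 41, 41)` is the full monitored
#'   session over which aerobic energy expenditure is integrated.
#' * Vector-magnitude cut-points: sedentary <= 199, light 200-2689,
#'   moderate 2690-6166, vigorous >= 6167 counts/min; MVPA >= 2690.
#' * Freedson-style vertical-axis energy equations gated at > 1951
#'   counts/min.
#' * Non-wear: >= 90 min of zero vector magnitude, tolerating spikes of
#'   <= 2 min flanked by >= 30 zero minutes each side.  Wear validity:
#'   >= 4 days with >= 600 wear minutes.
#'
#' @param file optional YAML or JSON file whose top-level keys override the
#'   defaults.
#' @param overrides named list of overrides applied after `file`.
#' @return a named list of constants with class `"eb_constants"`.
#' @examples
#' cc <- eb_constants(overrides = list(lactate_o2_equiv = 7.2))
#' cc$lactate_o2_equiv
#' @export
eb_constants <- function(file = NULL, overrides = list()) {
  cc <- list(
    kcal_per_litre_o2 = 5.05,
    kj_per_litre_o2 = 21.14,
    weir_a = 3.941,
    weir_b = 1.106,
    met_ml_per_kg_min = 3.5,
    lactate_o2_equiv = 3.0,
    sessions_per_week = 3,
    metabolic_duration_by_phase = c(18, 30, 36, 36),
    circuit_duration_by_phase = c(20, 33, 36, 36),
    session_duration_by_phase = c(23, 38, 41, 41),
    hrr_target_pct = 65,
    fat_energy_density_kcal_kg = 7700,
    activity_factor = 1.3,
    tef_fraction = 0,
    cutpoints = list(sedentary_max = 199, light_max = 2689,
                     moderate_max = 6166, vigorous_max = 9642),
    kcal_count_coef = 0.00094,
    kcal_mass_coef = 0.1346,
    kcal_intercept = -7.37418,
    kcal_count_gate = 1951,
    met_count_coef = 0.000795,
    met_intercept = 1.439008,
    met_count_gate = 1951,
    nonwear_window_min = 90,
    nonwear_spike_tolerance_min = 2,
    nonwear_spike_flank_min = 30,
    wear_min_days = 4,
    wear_min_minutes = 600,
    atwater = c(protein = 4, carbohydrate = 4, fat = 9),
    prescription_bands = list(cho_pct = c(55, 60), pro_pct = c(15, 20),
                              fat_pct = c(20, 25)),
    kcal_tolerance_pct = 5,
    macro_sum_tolerance = 2
  )
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    ov <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(file)
          else jsonlite::read_json(file, simplifyVector = TRUE)
    cc <- utils::modifyList(cc, ov)
  }
  if (length(overrides)) cc <- utils::modifyList(cc, overrides)
  structure(cc, class = c("eb_constants", "list"))
}

#' Training-protocol characteristics per phase
#'
#' The circuit protocol timing across the four training phases: session
#' duration, effort and recovery time, work/rest intervals, number of
#' exercises and rounds, inter-round rest, and the metabolic duration over
#' which per-session METs and kcal/min are expressed.  Effort time satisfies
#' `effort = session_duration - recovery` and the work:rest ratio equals
#' `work_interval_s / rest_interval_s`.
#'
#' @param constants an [eb_constants()] object supplying the per-phase
#'   metabolic durations.
#' @return a data frame with one row per phase (1-4).
#' @export
phase_protocols <- function(constants = eb_constants()) {
  pp <- data.frame(
    phase = 1:4,
    weeks = c("1-7", "8-14", "15-20", "21-40"),
    session_duration_min = c(23, 38, 41, 41),
    effort_min = c(6.66, 16.5, 24, 24),
    recovery_min = c(16.34, 21.5, 17, 17),
    work_interval_s = c(20, 30, 40, 40),
    rest_interval_s = c(40, 30, 20, 20),
    n_exercises = c(10, 11, 12, 12),
    n_rounds = c(2, 3, 3, 3),
    rest_per_round_min = c(3, 2.5, 2.5, 2),
    sessions_per_week = constants$sessions_per_week,
    metabolic_duration_min = constants$metabolic_duration_by_phase
  )
  stopifnot(all(abs(pp$effort_min - (pp$session_duration_min - pp$recovery_min)) < 1e-9),
            all(pp$metabolic_duration_min > 0))
  pp
}
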