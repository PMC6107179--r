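#' Resting metabolic rate from resting gas exchange (Weir equation)
#'
#' Converts steady-state resting oxygen uptake and carbon-dioxide output to a
#' 24-hour resting metabolic rate:
#' \deqn{RMR = (3.941\,VO_2 + 1.106\,VCO_2) \times 1440}
#' with gas volumes in L/min and the result in kcal/day.
#'
#' When `vo2 > 0` the respiratory exchange ratio `vco2/vo2` is checked
#' against the physiological range (0.6, 1.3) and a warning is issued
#' outside it.
#'
#' @param vo2 resting oxygen uptake, L/min (vectorised).
#' @param vco2 resting carbon-dioxide output, L/min.
#' @param constants an [eb_constants()] object (Weir coefficients).
#' @return resting metabolic rate, kcal/day.
#' @examples
#' weir_rmr(0.250, 0.200)  # 1737.3 kcal/day
#' @export
weir_rmr <- function(vo2, vco2, constants = eb_constants()) {
  if (any(vo2 < 0) || any(vco2 < 0))
    stop("gas exchange volumes must be nonnegative")
  pos <- vo2 > 0
  if (any(pos)) {
    rer <- vco2[pos] / vo2[pos]
    if (any(rer <= 0.6 | rer >= 1.3))
      warning("respiratory exchange ratio outside (0.6, 1.3); check inputs")
  }
  (constants$weir_a * vo2 + constants$weir_b * vco2) * 1440
}

#' Aerobic energy expenditure of an exercise bout
#'
#' Oxygen consumed above zero over the bout, converted to energy at a fixed
#' caloric equivalent (default 5.05 kcal, i.e. 21.14 kJ, per litre O2):
#' `mean_vo2 * mass_kg * duration_min / 1000 * kcal_per_litre`.
#' Linear (degree-1 homogeneous) in each argument.
#'
#' @param mean_vo2 mean exercise oxygen uptake, mL/kg/min.
#' @param mass_kg body mass, kg.
#' @param duration_min bout duration over which the mean VO2 applies, min.
#' @param kcal_per_litre caloric equivalent of oxygen, kcal/L.
#' @return energy expenditure, kcal.
#' @examples
#' aerobic_ee(23.84, 73.4, 36)  # ~318.1 kcal
#' @export
aerobic_ee <- function(mean_vo2, mass_kg, duration_min,
                       kcal_per_litre = eb_constants()$kcal_per_litre_o2) {
  if (any(mean_vo2 < 0) || any(mass_kg < 0) || any(duration_min < 0))
    stop("aerobic_ee inputs must be nonnegative")
  mean_vo2 * mass_kg * duration_min / 1000 * kcal_per_litre
}

#' Anaerobic (glycolytic) energy expenditure from blood-lactate accumulation
#'
#' Net lactate accumulation over a session is converted to an oxygen
#' equivalent (default 3.0 mL O2 per kg per mM) and then to energy.
#' Negative accumulation (post below pre, as can happen after recovery
#' sessions) clips to zero rather than erroring.
#'
#' @param lactate_pre,lactate_post blood lactate before and after the
#'   session, mM; both must be strictly positive.
#' @param mass_kg body mass, kg.
#' @param o2_equiv oxygen equivalent of lactate accumulation,
#'   mL O2 / kg / mM.
#' @param kcal_per_litre caloric equivalent of oxygen, kcal/L.
#' @return energy expenditure, kcal (>= 0).
#' @examples
#' anaerobic_ee(1.61, 8.99, 78)  # ~8.7 kcal at the 3.0 default
#' @export
anaerobic_ee <- function(lactate_pre, lactate_post, mass_kg,
                         o2_equiv = eb_constants()$lactate_o2_equiv,
                         kcal_per_litre = eb_constants()$kcal_per_litre_o2) {
  if (any(lactate_pre <= 0) || any(lactate_post <= 0))
    stop("lactate concentrations must be positive")
  if (any(mass_kg < 0)) stop("mass must be nonnegative")
  pmax(0, lactate_post - lactate_pre) * o2_equiv * mass_kg / 1000 * kcal_per_litre
}

#' Energy expenditure of excess post-exercise oxygen consumption
#'
#' Integrates a minute-sampled post-exercise VO2-above-rest trace by the
#' trapezoid rule (samples at minutes 0, 1, ..., n-1) and converts the
#' resulting oxygen volume to energy; alternatively accepts a
#' pre-integrated volume in litres, since many systems report only the
#' integral.
#'
#' @param trace numeric vector of VO2 above rest, L/min, sampled each
#'   minute; all values must be nonnegative.  An empty trace yields 0; a
#'   length-1 trace is treated as one minute at that rate.
#' @param volume_l pre-integrated EPOC volume, litres (used when `trace`
#'   is `NULL`).
#' @param kcal_per_litre caloric equivalent of oxygen, kcal/L.
#' @return energy expenditure, kcal.
#' @examples
#' epoc_kcal(volume_l = 2.18)         # ~11.0 kcal
#' epoc_kcal(trace = rep(0.3, 11))    # 3.0 L over 10 min -> 15.15 kcal
#' @export
epoc_kcal <- function(trace = NULL, volume_l = NULL,
                      kcal_per_litre = eb_constants()$kcal_per_litre_o2) {
  if (is.null(trace) && is.null(volume_l))
    stop("supply either a minute-sampled trace or a pre-integrated volume")
  if (!is.null(trace)) {
    if (any(trace < 0)) stop("EPOC trace values must be nonnegative")
    n <- length(trace)
    vol <- if (n == 0) 0
           else if (n == 1) trace
           else sum((trace[-1] + trace[-n]) / 2)
  } else {
    if (any(volume_l < 0)) stop("EPOC volume must be nonnegative")
    vol <- volume_l
  }
  vol * kcal_per_litre
}

#' Total energy expenditure of an exercise session
#'
#' The session total is the exact sum of its aerobic, anaerobic and EPOC
#' components (conservation: replacing any component by zero lowers the
#' total by exactly that component).
#'
#' @param aee aerobic energy expenditure, kcal.
#' @param anee anaerobic energy expenditure, kcal.
#' @param epoc EPOC energy expenditure, kcal.
#' @return total session energy expenditure, kcal.
#' @examples
#' session_tee(273.7, 27.0, 26.1)  # 326.8
#' @export
session_tee <- function(aee, anee, epoc) {
  if (any(aee < 0) || any(anee < 0) || any(epoc < 0))
    stop("energy components must be nonnegative")
  aee + anee + epoc
}

#' Metabolic equivalents from oxygen uptake
#'
#' Divides mean exercise VO2 by the conventional resting value of
#' 3.5 mL O2/kg/min.
#'
#' @param mean_vo2 mean oxygen uptake, mL/kg/min.
#' @param met_ml_per_kg_min the MET bridge, mL O2/kg/min.
#' @return intensity in METs.
#' @examples
#' mets_from_vo2(18.05)  # 5.16 METs
#' @export
mets_from_vo2 <- function(mean_vo2,
                          met_ml_per_kg_min = eb_constants()$met_ml_per_kg_min) {
  if (any(mean_vo2 < 0)) stop("mean_vo2 must be nonnegative")
  mean_vo2 / met_ml_per_kg_min
}

#' Per-session and weekly MET-hour training load
#'
#' `met_hours()` multiplies session intensity (METs) by the metabolic
#' duration in hours; `weekly_met_hours()` scales the per-session load by
#' the weekly session count (default 3).
#'
#' @param mets session intensity, METs.
#' @param metabolic_duration_min duration over which the METs are
#'   expressed, min.
#' @return MET-hours per session.
#' @examples
#' met_hours(6.75, 36)            # 4.05 MET-hours
#' weekly_met_hours(4.05)         # 12.15 MET-hours/week
#' @export
met_hours <- function(mets, metabolic_duration_min) {
  if (any(mets < 0) || any(metabolic_duration_min < 0))
    stop("inputs must be nonnegative")
  mets * metabolic_duration_min / 60
}

#' @rdname met_hours
#' @param met_hours_session per-session MET-hours.
#' @param sessions_per_week sessions per week.
#' @export
weekly_met_hours <- function(met_hours_session,
                             sessions_per_week = eb_constants()$sessions_per_week) {
  if (any(met_hours_session < 0) || any(sessions_per_week < 0))
    stop("inputs must be nonnegative")
  met_hours_session * sessions_per_week
}

#' Exercise-intensity expressions from heart rate
#'
#' Expresses a session's mean heart rate as a percentage of the maximal
#' heart rate obtained during aerobic-capacity testing and as a percentage
#' of heart-rate reserve (Karvonen), and flags whether the session met the
#' prescribed minimum of the heart-rate-reserve target (default 65%).
#'
#' @param mean_hr session mean heart rate, beats/min.
#' @param resting_hr resting heart rate, beats/min.
#' @param max_hr_test maximal heart rate from the graded exercise test,
#'   beats/min; must exceed `resting_hr`.
#' @param hrr_target_pct prescription threshold on %HRR.
#' @return list with `pct_max_hr`, `pct_hrr`, `meets_hrr_target`.
#' @examples
#' intensity_summary(143.2, 70, 164.9)  # pct_hrr ~ 77.1
#' @export
intensity_summary <- function(mean_hr, resting_hr, max_hr_test,
                              hrr_target_pct = eb_constants()$hrr_target_pct) {
  if (any(resting_hr >= max_hr_test))
    stop("resting_hr must be below max_hr_test")
  if (any(mean_hr < resting_hr) || any(mean_hr > max_hr_test))
    warning("mean_hr outside [resting_hr, max_hr_test]")
  pct_max <- mean_hr / max_hr_test * 100
  pct_hrr <- (mean_hr - resting_hr) / (max_hr_test - resting_hr) * 100
  list(pct_max_hr = pct_max, pct_hrr = pct_hrr,
       meets_hrr_target = pct_hrr >= hrr_target_pct)
}

#' Body mass index
#'
#' @param mass_kg body mass, kg.
#' @param height_m standing height, m (> 0).
#' @return BMI, kg/m^2.
#' @examples
#' bmi(78.0, 1.66)  # 28.3
#' @export
bmi <- function(mass_kg, height_m) {
  if (any(height_m <= 0)) stop("height must be positive")
  mass_kg / height_m^2
}

#' Waist-to-hip ratio
#'
#' @param waist_cm waist circumference, cm.
#' @param hip_cm hip circumference, cm (> 0).
#' @return waist/hip ratio.
#' @examples
#' whr(96.7, 110.9)  # 0.87
#' @export
whr <- function(waist_cm, hip_cm) {
  if (any(hip_cm <= 0)) stop("hip circumference must be positive")
  if (any(waist_cm < 0)) stop("waist circumference must be nonnegative")
  waist_cm / hip_cm
}

#' Validate an anthropometry record
#'
#' Checks internal consistency of an anthropometry data frame: DXA fat mass
#' plus fat-free mass should equal body mass within tolerance (default 5%,
#' warning otherwise), height must be plausible (1.2-2.2 m) and
#' circumferences positive.
#'
#' @param anth data frame with columns `mass_kg`, `height_m`, and
#'   optionally `fat_mass_kg`, `ffm_kg`, `waist_cm`, `hip_cm`.
#' @param dxa_tolerance relative tolerance on fat + ffm vs mass.
#' @return `anth`, invisibly, after checks.
#' @export
validate_anthropometry <- function(anth, dxa_tolerance = 0.05) {
  stopifnot(is.data.frame(anth), all(c("mass_kg", "height_m") %in% names(anth)))
  if (any(anth$height_m <= 1.2 | anth$height_m >= 2.2))
    stop("height outside plausible (1.2, 2.2) m range")
  for (col in c("waist_cm", "hip_cm"))
    if (col %in% names(anth) && any(anth[[col]] <= 0))
      stop(sprintf("%s must be positive", col))
  if (all(c("fat_mass_kg", "ffm_kg") %in% names(anth))) {
    rel <- abs(anth$fat_mass_kg + anth$ffm_kg - anth$mass_kg) / anth$mass_kg
    if (any(rel > dxa_tolerance))
      warning("fat mass + fat-free mass differs from body mass by more than DXA tolerance")
  }
  invisible(anth)
}
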