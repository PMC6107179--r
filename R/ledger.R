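#' Daily energy balance
#'
#' The accounting identity behind the trial's energy-balance figures:
#' `balance = intake - (RMR + habitual activity + exercise)`, positive for a
#' surplus.  A day is typed "exercise" exactly when `exercise_kcal > 0`.
#' The thermic effect of food is excluded by default; an optional fixed
#' fraction of intake can be added to expenditure via `tef_fraction`.
#'
#' @param intake_kcal energy intake, kcal.
#' @param rmr_kcal resting metabolic rate over the day, kcal.
#' @param activity_kcal habitual (non-exercise) activity energy, kcal.
#' @param exercise_kcal exercise-session energy, kcal (0 on non-exercise
#'   days).
#' @param date optional date label.
#' @param tef_fraction fraction of intake charged as thermic effect of
#'   food (default 0, mirroring designs that do not measure it).
#' @return one-row data frame (`date`, `day_type`, components,
#'   `balance_kcal`).
#' @examples
#' day_balance(1807, 1536, 165, 385)$balance_kcal  # -279
#' @export
day_balance <- function(intake_kcal, rmr_kcal, activity_kcal,
                        exercise_kcal = 0, date = NA,
                        tef_fraction = eb_constants()$tef_fraction) {
  if (any(c(intake_kcal, rmr_kcal, activity_kcal, exercise_kcal) < 0))
    stop("energy components must be nonnegative")
  tef <- tef_fraction * intake_kcal
  data.frame(
    date = date,
    day_type = ifelse(exercise_kcal > 0, "exercise", "non-exercise"),
    intake_kcal = intake_kcal,
    rmr_kcal = rmr_kcal,
    activity_kcal = activity_kcal,
    exercise_kcal = exercise_kcal,
    balance_kcal = intake_kcal - (rmr_kcal + activity_kcal + exercise_kcal + tef)
  )
}

#' Weekly energy balance from typical exercise and non-exercise days
#'
#' `n_exercise_days` copies of the exercise-day balance plus the remaining
#' days of the non-exercise balance; linear in both balances.
#'
#' @param exercise_day a [day_balance()] row or a numeric balance, kcal.
#' @param nonexercise_day a [day_balance()] row or a numeric balance, kcal.
#' @param n_exercise_days exercise days per week (0-7; default 3).
#' @return weekly balance, kcal/week.
#' @examples
#' week_balance(-279, 106)  # -413 kcal/week
#' @export
week_balance <- function(exercise_day, nonexercise_day, n_exercise_days = 3) {
  if (n_exercise_days < 0 || n_exercise_days > 7)
    stop("n_exercise_days must be between 0 and 7")
  bal <- function(x) if (is.data.frame(x)) x$balance_kcal else x
  n_exercise_days * bal(exercise_day) + (7 - n_exercise_days) * bal(nonexercise_day)
}

#' Fat-mass equivalent of a cumulative energy balance
#'
#' Converts a cumulative balance to a fat-mass equivalent at a fixed energy
#' density (default 7700 kcal/kg of adipose tissue) and a per-week rate.
#' Sign is retained: a deficit (negative balance) yields a negative
#' fat-mass change.
#'
#' @param total_balance_kcal cumulative balance over the period, kcal.
#' @param weeks period length, weeks (> 0).
#' @param energy_density_kcal_kg energy density of fat mass, kcal/kg (> 0).
#' @return list with `fat_equivalent_kg` and `fat_rate_kg_per_week`.
#' @examples
#' period_fat_equivalent(-42700, 40)  # ~ -5.5 kg, ~ -0.14 kg/week
#' @export
period_fat_equivalent <- function(total_balance_kcal, weeks,
                                  energy_density_kcal_kg = eb_constants()$fat_energy_density_kcal_kg) {
  if (weeks <= 0) stop("weeks must be positive")
  if (energy_density_kcal_kg <= 0) stop("energy density must be positive")
  kg <- total_balance_kcal / energy_density_kcal_kg
  list(fat_equivalent_kg = kg, fat_rate_kg_per_week = kg / weeks)
}

#' Period roll-up of a daily ledger
#'
#' Sums daily balances over any set of ledger days — the ledger is an exact
#' accounting identity, so the period total equals the sum of daily
#' balances with no drift — and attaches the fat-mass equivalent.
#'
#' @param days data frame of [day_balance()] rows.
#' @param weeks period length in weeks; defaults to `nrow(days) / 7`.
#' @param energy_density_kcal_kg energy density of fat mass, kcal/kg.
#' @return list with `total_balance_kcal`, `weekly_balance_kcal` (mean),
#'   `weeks`, `fat_equivalent_kg`, `fat_rate_kg_per_week`.
#' @export
period_balance <- function(days, weeks = nrow(days) / 7,
                           energy_density_kcal_kg = eb_constants()$fat_energy_density_kcal_kg) {
  stopifnot(is.data.frame(days), "balance_kcal" %in% names(days))
  total <- sum(days$balance_kcal)
  fe <- period_fat_equivalent(total, weeks, energy_density_kcal_kg)
  c(list(total_balance_kcal = total,
         weekly_balance_kcal = total / weeks,
         weeks = weeks), fe)
}
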