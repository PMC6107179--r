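#' Read a diet-recall CSV
#'
#' Columns: `subject_id` (optional), `date`, `protein_g`, `carbohydrate_g`,
#' `fat_g` and optionally `energy_kcal`.  If `energy_kcal` is supplied it is
#' checked against the Atwater reconstruction `4P + 4C + 9F` and a warning
#' is raised when any day disagrees by more than 5%.
#'
#' @param path CSV file path.
#' @param constants an [eb_constants()] object (Atwater factors).
#' @return data frame of recall days.
#' @export
read_recall_csv <- function(path, constants = eb_constants()) {
  rc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_g", "carbohydrate_g", "fat_g")
  miss <- setdiff(need, names(rc))
  if (length(miss)) stop("recall file missing columns: ", paste(miss, collapse = ", "))
  validate_recalls(rc, constants)
}

#' @keywords internal
validate_recalls <- function(rc, constants = eb_constants()) {
  for (col in c("protein_g", "carbohydrate_g", "fat_g")) {
    bad <- which(rc[[col]] < 0)
    if (length(bad)) stop(sprintf("negative %s at row %d", col, bad[1]))
  }
  if ("energy_kcal" %in% names(rc)) {
    atw <- constants$atwater
    recon <- atw[["protein"]] * rc$protein_g +
      atw[["carbohydrate"]] * rc$carbohydrate_g + atw[["fat"]] * rc$fat_g
    off <- abs(rc$energy_kcal - recon) / pmax(recon, 1) > 0.05
    if (any(off))
      warning(sprintf("%d recall day(s) disagree with 4/4/9 reconstruction by >5%%",
                      sum(off)))
  }
  rc
}

#' Mean daily energy intake and macronutrient shares
#'
#' Daily energy is always recomputed from macro grams with Atwater factors
#' (4/4/9 kcal/g); the reported intake is the mean of the daily energies.
#' Macronutrient percentages are computed on an energy basis from the grams
#' summed over the whole period (not as a mean of daily percentages), so
#' they always sum to 100 up to rounding.
#'
#' @param recalls data frame of recall days (>= 1 row) with columns
#'   `protein_g`, `carbohydrate_g`, `fat_g`.
#' @param constants an [eb_constants()] object.
#' @return list with `energy_kcal_day`, `pro_pct`, `cho_pct`, `fat_pct`,
#'   `n_days`.
#' @examples
#' mean_energy_intake(data.frame(protein_g = 75, carbohydrate_g = 260, fat_g = 50))
#' @export
mean_energy_intake <- function(recalls, constants = eb_constants()) {
  if (!is.data.frame(recalls) || nrow(recalls) == 0)
    stop("at least one recall day is required")
  recalls <- validate_recalls(recalls, constants)
  atw <- constants$atwater
  daily <- atw[["protein"]] * recalls$protein_g +
    atw[["carbohydrate"]] * recalls$carbohydrate_g +
    atw[["fat"]] * recalls$fat_g
  pk <- atw[["protein"]] * sum(recalls$protein_g)
  ck <- atw[["carbohydrate"]] * sum(recalls$carbohydrate_g)
  fk <- atw[["fat"]] * sum(recalls$fat_g)
  tot <- pk + ck + fk
  list(energy_kcal_day = mean(daily),
       pro_pct = if (tot > 0) pk / tot * 100 else 0,
       cho_pct = if (tot > 0) ck / tot * 100 else 0,
       fat_pct = if (tot > 0) fk / tot * 100 else 0,
       n_days = nrow(recalls))
}

#' Isocaloric intake target from resting metabolic rate
#'
#' Weight-maintenance energy target as RMR times a habitual-activity
#' factor (default 1.3, sedentary-to-light; the factor is a configurable
#' assumption and is re-derivable at re-assessment).
#'
#' @param rmr_kcal_day resting metabolic rate, kcal/day (> 0).
#' @param activity_factor habitual-activity multiplier.
#' @return target intake, kcal/day.
#' @examples
#' isocaloric_target(1451.6, 1.27)  # ~1843.5
#' @export
isocaloric_target <- function(rmr_kcal_day,
                              activity_factor = eb_constants()$activity_factor) {
  if (any(rmr_kcal_day <= 0)) stop("RMR must be positive")
  if (any(activity_factor <= 0)) stop("activity factor must be positive")
  rmr_kcal_day * activity_factor
}

#' Check an intake summary against the isocaloric prescription
#'
#' Compares a [mean_energy_intake()] summary against the prescription bands
#' (carbohydrate 55-60%, protein 15-20%, fat 20-25% of energy) and, when a
#' target is given, against `target_kcal` within a relative tolerance
#' (default 5%).  Macro percentages must sum to approximately 100 (within
#' `macro_sum_tolerance` points) before banding; otherwise the summary is
#' rejected outright.
#'
#' @param summary list from [mean_energy_intake()].
#' @param target_kcal prescribed daily energy, kcal (optional).
#' @param kcal_tolerance_pct relative energy tolerance, percent.
#' @param constants an [eb_constants()] object (bands, tolerances).
#' @return data frame with one row per criterion: `criterion`, `value`,
#'   `pass`.
#' @export
prescription_check <- function(summary, target_kcal = NULL,
                               kcal_tolerance_pct = eb_constants()$kcal_tolerance_pct,
                               constants = eb_constants()) {
  bands <- constants$prescription_bands
  if (summary$energy_kcal_day <= 0) {
    crit <- c("carbohydrate_pct", "protein_pct", "fat_pct")
    if (!is.null(target_kcal)) crit <- c(crit, "energy_kcal")
    return(data.frame(criterion = crit, value = 0, pass = FALSE))
  }
  macro_sum <- summary$pro_pct + summary$cho_pct + summary$fat_pct
  if (abs(macro_sum - 100) > constants$macro_sum_tolerance)
    stop(sprintf("macro percentages sum to %.1f; must be ~100 before banding",
                 macro_sum))
  in_band <- function(x, b) x >= b[1] & x <= b[2]
  rows <- data.frame(
    criterion = c("carbohydrate_pct", "protein_pct", "fat_pct"),
    value = c(summary$cho_pct, summary$pro_pct, summary$fat_pct),
    pass = c(in_band(summary$cho_pct, bands$cho_pct),
             in_band(summary$pro_pct, bands$pro_pct),
             in_band(summary$fat_pct, bands$fat_pct))
  )
  if (!is.null(target_kcal)) {
    ok <- abs(summary$energy_kcal_day - target_kcal) <=
      target_kcal * kcal_tolerance_pct / 100
    rows <- rbind(rows, data.frame(criterion = "energy_kcal",
                                   value = summary$energy_kcal_day,
                                   pass = ok))
  }
  rows
}
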