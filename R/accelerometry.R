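#' Read a 60-s epoch accelerometer count file
#'
#' Reads an ActiGraph-export-like CSV with a header row and columns
#' `timestamp`, `axis1`, `axis2`, `axis3`, optional `vm` and `steps`.  A
#' missing vector-magnitude column is computed as
#' `sqrt(axis1^2 + axis2^2 + axis3^2)`.  Counts must be nonnegative and
#' timestamps strictly increasing at minute resolution.
#'
#' @param path CSV file path.
#' @return data frame of epochs with a POSIXct `timestamp` column.
#' @export
read_epoch_csv <- function(path) {
  ep <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "axis1", "axis2", "axis3")
  miss <- setdiff(need, names(ep))
  if (length(miss)) stop("epoch file missing columns: ", paste(miss, collapse = ", "))
  ep$timestamp <- parse_timestamp(ep$timestamp)
  if (anyNA(ep$timestamp)) stop("unparseable timestamps in ", path)
  validate_epochs(ep)
}

#' @keywords internal
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  ts <- as.POSIXct(x, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  i <- is.na(ts)
  if (any(i)) ts[i] <- as.POSIXct(x[i], tz = "UTC")
  ts
}

#' @keywords internal
validate_epochs <- function(ep) {
  for (col in intersect(c("axis1", "axis2", "axis3", "vm", "steps"), names(ep))) {
    bad <- which(ep[[col]] < 0)
    if (length(bad))
      stop(sprintf("negative %s at row %d", col, bad[1]))
  }
  if (is.unsorted(ep$timestamp, strictly = TRUE))
    stop("epoch timestamps must be strictly increasing")
  if (!"vm" %in% names(ep) || all(is.na(ep$vm)))
    ep$vm <- sqrt(ep$axis1^2 + ep$axis2^2 + ep$axis3^2)
  if (!"steps" %in% names(ep)) ep$steps <- 0L
  ep
}

#' Label non-wear epochs in a vector-magnitude stream
#'
#' A minute is non-wear when it lies inside a run of at least `window_min`
#' consecutive zero vector-magnitude minutes, where nonzero interruptions of
#' up to `spike_tolerance_min` consecutive minutes are tolerated (counted as
#' part of the run) provided they are flanked on both sides by at least
#' `spike_flank_min` zero minutes.  The defaults (90/2/30) follow the
#' widely used vector-magnitude non-wear convention for 60-s epochs.
#' The labelling is a pure function of the count stream and therefore
#' idempotent.
#'
#' @param vm numeric vector of per-minute vector-magnitude counts, in
#'   chronological order (one contiguous stream).
#' @param window_min minimum run length, minutes.
#' @param spike_tolerance_min maximum tolerated nonzero interruption,
#'   minutes.
#' @param spike_flank_min zero minutes required on each side of a
#'   tolerated interruption.
#' @return logical vector, `TRUE` where the epoch is non-wear.
#' @examples
#' sum(detect_nonwear(rep(0, 120)))  # all 120 labelled non-wear
#' @export
detect_nonwear <- function(vm,
                           window_min = eb_constants()$nonwear_window_min,
                           spike_tolerance_min = eb_constants()$nonwear_spike_tolerance_min,
                           spike_flank_min = eb_constants()$nonwear_spike_flank_min) {
  n <- length(vm)
  if (n == 0) return(logical(0))
  if (any(vm < 0)) stop("vector-magnitude counts must be nonnegative")
  r <- rle(vm == 0)
  vals <- r$values
  lens <- r$lengths
  k <- length(vals)
  for (j in seq_len(k)) {
    if (!vals[j] && lens[j] <= spike_tolerance_min &&
        j > 1 && j < k &&
        r$values[j - 1] && r$lengths[j - 1] >= spike_flank_min &&
        r$values[j + 1] && r$lengths[j + 1] >= spike_flank_min) {
      vals[j] <- TRUE  # absorb tolerated spike into the zero run
    }
  }
  z <- inverse.rle(list(values = vals, lengths = lens))
  r2 <- rle(z)
  lab <- r2$values & r2$lengths >= window_min
  inverse.rle(list(values = lab, lengths = r2$lengths))
}

#' Classify per-minute counts into intensity bands
#'
#' Vector-magnitude cut-points: sedentary <= 199, light 200-2689, moderate
#' 2690-6166, vigorous >= 6167 counts/min (the upper vigorous edge is a
#' reporting bound, not a cap).  Moderate-to-vigorous activity is
#' `vm >= 2690`.
#'
#' @param vm nonnegative counts/min.
#' @param constants an [eb_constants()] object holding the cut-points.
#' @return factor with levels sedentary/light/moderate/vigorous.
#' @examples
#' classify_intensity(c(0, 2689, 2690, 6167))
#' @export
classify_intensity <- function(vm, constants = eb_constants()) {
  if (any(vm < 0)) stop("counts must be nonnegative")
  cp <- constants$cutpoints
  cut(vm, breaks = c(-Inf, cp$sedentary_max, cp$light_max, cp$moderate_max, Inf),
      labels = c("sedentary", "light", "moderate", "vigorous"))
}

#' @rdname classify_intensity
#' @export
is_mvpa <- function(vm, constants = eb_constants()) {
  vm > constants$cutpoints$light_max
}

#' Summarise one calendar day of wear-labelled epochs
#'
#' Over wear epochs only: sums steps and the minutes spent in each
#' intensity band (the bands partition wear time; MVPA = moderate +
#' vigorous), accumulates activity kilocalories with a Freedson-style
#' vertical-axis equation (`0.00094*axis1 + 0.1346*mass - 7.37418`
#' kcal/min, applied when axis1 exceeds 1951 counts/min, floored at zero),
#' and averages per-epoch METs (`0.000795*axis1 + 1.439008` above the gate,
#' else 1.0).  A day with zero wear minutes is returned with
#' `mean_mets = NA` and flagged.
#'
#' @param epochs one day of epoch records (as from [read_epoch_csv()]).
#' @param mass_kg body mass, kg.
#' @param wear logical wear labels; defaults to `!detect_nonwear(epochs$vm)`.
#' @param constants an [eb_constants()] object.
#' @return one-row data frame (a day summary).
#' @export
summarize_day <- function(epochs, mass_kg, wear = NULL,
                          constants = eb_constants()) {
  o <- order(epochs$timestamp)   # summaries are order-invariant
  epochs <- epochs[o, , drop = FALSE]
  if (!is.null(wear)) wear <- wear[o]
  epochs <- validate_epochs(epochs)
  if (is.null(wear)) wear <- !detect_nonwear(epochs$vm,
                                             constants$nonwear_window_min,
                                             constants$nonwear_spike_tolerance_min,
                                             constants$nonwear_spike_flank_min)
  stopifnot(length(wear) == nrow(epochs))
  w <- epochs[wear, , drop = FALSE]
  band <- classify_intensity(w$vm, constants)
  mins <- table(band)
  kcal_min <- ifelse(w$axis1 > constants$kcal_count_gate,
                     pmax(0, constants$kcal_count_coef * w$axis1 +
                             constants$kcal_mass_coef * mass_kg +
                             constants$kcal_intercept),
                     0)
  mets_min <- ifelse(w$axis1 > constants$met_count_gate,
                     constants$met_count_coef * w$axis1 + constants$met_intercept,
                     1.0)
  wear_min <- nrow(w)
  out <- data.frame(
    date = as.Date(epochs$timestamp[1]),
    wear_min = wear_min,
    steps = sum(w$steps),
    sedentary_min = as.integer(mins[["sedentary"]]),
    light_min = as.integer(mins[["light"]]),
    moderate_min = as.integer(mins[["moderate"]]),
    vigorous_min = as.integer(mins[["vigorous"]]),
    mvpa_min = as.integer(mins[["moderate"]] + mins[["vigorous"]]),
    activity_kcal = sum(kcal_min),
    mean_mets = if (wear_min > 0) mean(mets_min) else NA_real_,
    zero_wear = wear_min == 0
  )
  out
}

#' Summarise a multi-day epoch stream per calendar day
#'
#' Splits an epoch stream by calendar date, labels non-wear on the full
#' stream, and summarises each day with [summarize_day()].  First and last
#' partial days (fewer than 1440 epochs) can be dropped from validity
#' counting downstream via the `partial` flag added here.
#'
#' @inheritParams summarize_day
#' @return data frame of day summaries with a `partial` column.
#' @export
summarize_days <- function(epochs, mass_kg, constants = eb_constants()) {
  epochs <- validate_epochs(epochs)
  wear <- !detect_nonwear(epochs$vm,
                          constants$nonwear_window_min,
                          constants$nonwear_spike_tolerance_min,
                          constants$nonwear_spike_flank_min)
  dt <- as.Date(epochs$timestamp)
  idx <- split(seq_len(nrow(epochs)), dt)
  days <- do.call(rbind, lapply(idx, function(i)
    summarize_day(epochs[i, , drop = FALSE], mass_kg, wear = wear[i],
                  constants = constants)))
  rownames(days) <- NULL
  days$partial <- vapply(idx, length, 1L) < 1440
  days
}

#' Apply the wear-time validity rule to day summaries
#'
#' Drops days with fewer than `min_wear_min` wear minutes (default 600,
#' i.e. 10 h) and partial boundary days, then declares the subject valid
#' when at least `min_days` (default 4) days remain.  Boundaries are
#' inclusive: exactly 4 days of exactly 600 minutes is valid.
#'
#' @param days data frame of day summaries from [summarize_days()].
#' @param min_days minimum retained days for validity.
#' @param min_wear_min minimum wear minutes per retained day.
#' @return list with `days` (retained subset) and `valid` (logical).
#' @export
valid_wear_filter <- function(days,
                              min_days = eb_constants()$wear_min_days,
                              min_wear_min = eb_constants()$wear_min_minutes) {
  stopifnot(is.data.frame(days), nrow(days) >= 1)
  keep <- days$wear_min >= min_wear_min
  if ("partial" %in% names(days)) keep <- keep & !days$partial
  retained <- days[keep, , drop = FALSE]
  list(days = retained, valid = nrow(retained) >= min_days)
}
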