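#' Load a synthetic-trial configuration
#'
#' Reads the versioned YAML of distributional targets that defines the
#' emulated trial — group sizes, baseline anthropometry, per-phase session
#' physiology, habitual-activity and intake targets, and per-group
#' per-timepoint outcome trajectories — and validates its internal
#' consistency (positive group sizes, nonnegative SDs, session heart rate
#' and VO2 nondecreasing over training phases 1-3, macro split summing to
#' 100).
#'
#' @param file YAML file; defaults to the configuration shipped with the
#'   package.
#' @param overrides named list merged over the file contents (e.g. smaller
#'   group sizes for quick experiments).
#' @return a list of class `"eb_trial_config"`.
#' @export
trial_config <- function(file = system.file("extdata", "trial_defaults.yaml",
                                            package = "enerbal"),
                         overrides = list()) {
  cfg <- yaml::read_yaml(file)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  stopifnot(all(unlist(cfg$design$groups) >= 2))
  for (o in names(cfg$outcomes)) for (g in names(cfg$outcomes[[o]]))
    if (any(cfg$outcomes[[o]][[g]]$sd < 0))
      stop("negative SD in outcome profile: ", o)
  hr <- vapply(cfg$phases, function(p) p$mean_hr[1], 1)
  vo2 <- vapply(cfg$phases, function(p) p$vo2[1], 1)
  stopifnot(!is.unsorted(hr[1:3]), !is.unsorted(vo2[1:3]))
  ms <- cfg$intake$macro_split
  stopifnot(abs(ms$cho + ms$pro + ms$fat - 100) < 1e-6)
  structure(cfg, class = c("eb_trial_config", "list"))
}

#' @keywords internal
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (lo >= hi) stop("impossible truncation bounds")
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort with baseline assessments
#'
#' Draws per-group subjects from truncated normal baselines (+/- 3 SD by
#' default): age, body mass, body-fat percentage, waist and hip
#' circumference, aerobic capacity, leg-press strength, habitual steps and
#' MVPA targets, RMR and resting heart rate.  Height is drawn from its
#' truncated normal further constrained, given the drawn mass, so that BMI
#' falls inside the trial's inclusion window — emulating an eligibility
#' screen.  Records are internally consistent: fat mass + fat-free mass =
#' body mass and BMI = mass / height^2.  Resting gas exchange is derived by
#' inverting the Weir equation at a drawn resting respiratory exchange
#' ratio.  Identical `(config, seed)` pairs give identical cohorts.
#'
#' @param config an [trial_config()] object.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @param constants an [eb_constants()] object.
#' @return data frame with one row per subject.
#' @export
gen_cohort <- function(config = trial_config(), seed = NULL,
                       constants = eb_constants()) {
  if (!is.null(seed)) set.seed(seed)
  ts <- config$design$truncation_sd
  bwin <- config$inclusion$bmi_window
  draw <- function(ms, n) rtrunc_norm(n, ms[1], ms[2],
                                      ms[1] - ts * ms[2], ms[1] + ts * ms[2])
  base_out <- function(o, g) {
    p <- config$outcomes[[o]][[g]]
    c(p$mean[1], p$sd[1])
  }
  rows <- lapply(names(config$design$groups), function(g) {
    n <- config$design$groups[[g]]
    age <- draw(unlist(config$baseline$age[[g]]), n)
    mass <- draw(base_out("body_mass", g), n)
    hm <- unlist(config$baseline$height_m[[g]])
    height <- vapply(mass, function(m) {
      blo <- sqrt(m / bwin[2]); bhi <- sqrt(m / bwin[1])
      lo <- max(hm[1] - ts * hm[2], blo)
      hi <- min(hm[1] + ts * hm[2], bhi)
      if (lo >= hi) { lo <- blo; hi <- bhi }  # eligibility screen dominates
      rtrunc_norm(1, hm[1], hm[2], lo, hi)
    }, 1)
    bf <- draw(base_out("body_fat_pct", g), n)
    rmr <- draw(base_out("rmr", g), n)
    rer <- draw(unlist(config$baseline$resting_rer[[g]]), n)
    vo2_rest <- rmr / 1440 / (constants$weir_a + constants$weir_b * rer)
    steps <- pmax(500, draw(c(config$activity$steps[[g]][1],
                              config$activity$steps_sd[[g]]), n))
    mvpa <- pmax(1, draw(c(config$activity$mvpa_min[[g]][1],
                           config$activity$mvpa_sd[[g]]), n))
    rhr <- draw(unlist(config$baseline$resting_hr[[g]]), n)
    data.frame(
      subject_id = sprintf("%s%02d", g, seq_len(n)),
      group = g, age = age, height_m = height, mass_kg = mass,
      bmi = mass / height^2, body_fat_pct = bf,
      fat_mass_kg = mass * bf / 100, ffm_kg = mass * (1 - bf / 100),
      waist_cm = draw(base_out("waist", g), n),
      hip_cm = draw(base_out("hip", g), n),
      steps_day = steps, mvpa_min_day = mvpa,
      vo2max = draw(base_out("vo2max", g), n),
      one_rm = draw(base_out("one_rm", g), n),
      rmr_kcal = rmr, resting_rer = rer,
      resting_vo2 = vo2_rest, resting_vco2 = rer * vo2_rest,
      resting_hr = rhr,
      max_hr_test = 220 - age + stats::rnorm(n, 0, 7),
      ei_target_kcal = rep(config$intake$ei_kcal[[g]][1], n)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate monitored-session physiology for one training phase
#'
#' One monitored session per training subject: mean and maximal session
#' heart rate (max >= mean enforced), blood lactate before, mid- and
#' post-session with the ordering `mid >= pre` and `post >= pre` enforced
#' by truncation, mean session VO2, minute ventilation, RER, perceived
#' exertion (Borg 6-20), and an EPOC volume in litres whose energy
#' equivalent is centred on the phase target.  Distributional targets come
#' from the phase table of the configuration and rise across phases 1-3.
#'
#' @param cohort data frame from [gen_cohort()]; only rows in `groups` are
#'   used.
#' @param phase training phase, 1-4.
#' @param config an [trial_config()] object.
#' @param seed integer seed, or `NULL`.
#' @param groups groups that train (default TR and TRD; TRD stops after
#'   phase 3 when `detraining = TRUE`).
#' @param constants an [eb_constants()] object.
#' @return data frame of session records.
#' @export
gen_sessions <- function(cohort, phase, config = trial_config(), seed = NULL,
                         groups = c("TR", "TRD"), constants = eb_constants()) {
  stopifnot(phase %in% 1:4)
  if (!is.null(seed)) set.seed(seed)
  if (phase == 4) groups <- setdiff(groups, "TRD")  # detraining arm stops
  ph <- config$phases[[phase]]
  sub <- cohort[cohort$group %in% groups, , drop = FALSE]
  n <- nrow(sub)
  mean_hr <- rtrunc_norm(n, ph$mean_hr[1], ph$mean_hr[2],
                         ph$mean_hr[1] - 3 * ph$mean_hr[2],
                         ph$mean_hr[1] + 3 * ph$mean_hr[2])
  max_hr <- vapply(seq_len(n), function(i)
    rtrunc_norm(1, ph$max_hr[1], ph$max_hr[2], mean_hr[i],
                max(ph$max_hr[1] + 3 * ph$max_hr[2], mean_hr[i] + 1)), 1)
  pre <- rtrunc_norm(n, ph$lactate_pre[1], ph$lactate_pre[2],
                     max(0.2, ph$lactate_pre[1] - 3 * ph$lactate_pre[2]),
                     ph$lactate_pre[1] + 3 * ph$lactate_pre[2])
  mid <- vapply(seq_len(n), function(i)
    rtrunc_norm(1, ph$lactate_mid[1], ph$lactate_mid[2], pre[i],
                max(ph$lactate_mid[1] + 3 * ph$lactate_mid[2], pre[i] + 0.1)), 1)
  post <- vapply(seq_len(n), function(i)
    rtrunc_norm(1, ph$lactate_post[1], ph$lactate_post[2], pre[i],
                max(ph$lactate_post[1] + 3 * ph$lactate_post[2], pre[i] + 0.1)), 1)
  epoc_l <- rtrunc_norm(n, ph$epoc_kcal[1] / constants$kcal_per_litre_o2,
                        ph$epoc_kcal[2] / constants$kcal_per_litre_o2,
                        0.05, (ph$epoc_kcal[1] + 3 * ph$epoc_kcal[2]) /
                          constants$kcal_per_litre_o2)
  data.frame(
    subject_id = sub$subject_id, group = sub$group, phase = phase,
    mean_hr = mean_hr, max_hr = max_hr,
    lactate_pre = pre, lactate_mid = mid, lactate_post = post,
    mean_vo2_mlkgmin = rtrunc_norm(n, ph$vo2[1], ph$vo2[2],
                                   max(1, ph$vo2[1] - 3 * ph$vo2[2]),
                                   ph$vo2[1] + 3 * ph$vo2[2]),
    ve_lmin = rtrunc_norm(n, ph$ve[1], ph$ve[2],
                          max(5, ph$ve[1] - 3 * ph$ve[2]),
                          ph$ve[1] + 3 * ph$ve[2]),
    rer = rtrunc_norm(n, ph$rer[1], ph$rer[2],
                      ph$rer[1] - 3 * ph$rer[2], ph$rer[1] + 3 * ph$rer[2]),
    rpe = rtrunc_norm(n, ph$rpe[1], ph$rpe[2], 6, 20),
    epoc_litres = epoc_l
  )
}

#' Energy decomposition and training-load chain for session records
#'
#' Runs the physiological arithmetic over monitored-session records:
#' aerobic energy over the full session duration of the phase, anaerobic
#' energy from pre-to-post lactate accumulation, EPOC energy from the
#' recorded oxygen volume, their sum (session total), METs from mean VO2,
#' per-session and weekly MET-hours and kcal/min over the phase's
#' metabolic duration, and heart-rate intensity expressions against each
#' subject's resting and test-maximal heart rate.
#'
#' @param sessions data frame from [gen_sessions()] or read from a session
#'   CSV (columns `subject_id`, `phase`, `mean_hr`, `lactate_pre`,
#'   `lactate_post`, `mean_vo2_mlkgmin`, `epoc_litres`).
#' @param cohort subject table supplying `mass_kg`, `resting_hr`,
#'   `max_hr_test` per `subject_id`.
#' @param constants an [eb_constants()] object.
#' @return `sessions` with columns `aee_kcal`, `anee_kcal`, `epoc_kcal`,
#'   `tee_kcal`, `mets`, `met_hours`, `weekly_met_hours`, `ee_kcal_min`,
#'   `pct_max_hr`, `pct_hrr` appended.
#' @export
session_energy <- function(sessions, cohort, constants = eb_constants()) {
  i <- match(sessions$subject_id, cohort$subject_id)
  if (anyNA(i)) stop("sessions reference unknown subjects")
  mass <- cohort$mass_kg[i]
  sdur <- constants$session_duration_by_phase[sessions$phase]
  mdur <- constants$metabolic_duration_by_phase[sessions$phase]
  sessions$aee_kcal <- aerobic_ee(sessions$mean_vo2_mlkgmin, mass, sdur,
                                  constants$kcal_per_litre_o2)
  sessions$anee_kcal <- anaerobic_ee(sessions$lactate_pre, sessions$lactate_post,
                                     mass, constants$lactate_o2_equiv,
                                     constants$kcal_per_litre_o2)
  sessions$epoc_kcal <- epoc_kcal(volume_l = sessions$epoc_litres,
                                  kcal_per_litre = constants$kcal_per_litre_o2)
  sessions$tee_kcal <- session_tee(sessions$aee_kcal, sessions$anee_kcal,
                                   sessions$epoc_kcal)
  sessions$mets <- mets_from_vo2(sessions$mean_vo2_mlkgmin,
                                 constants$met_ml_per_kg_min)
  sessions$met_hours <- met_hours(sessions$mets, mdur)
  sessions$weekly_met_hours <- weekly_met_hours(sessions$met_hours,
                                                constants$sessions_per_week)
  sessions$ee_kcal_min <- sessions$tee_kcal / mdur
  it <- intensity_summary(sessions$mean_hr, cohort$resting_hr[i],
                          cohort$max_hr_test[i], constants$hrr_target_pct)
  sessions$pct_max_hr <- it$pct_max_hr
  sessions$pct_hrr <- it$pct_hrr
  sessions
}

#' Generate a week of 60-s epoch accelerometer counts
#'
#' Emulates habitual activity as a two-state (active/inactive) Markov
#' chain over full-day wear, with lognormal vector-magnitude counts within
#' state.  Active minutes split between light and moderate-to-vigorous
#' intensity so the expected MVPA minutes match the target; per-minute step
#' counts are Poisson with cadences calibrated so expected daily steps
#' match the target.  Optional non-wear blocks (device off) zero the
#' counts.  Infeasible targets (more active minutes than the day holds)
#' raise an error.
#'
#' @param steps_day target steps per day.
#' @param mvpa_min_day target moderate-to-vigorous minutes per day.
#' @param light_min_day target light-intensity minutes per day.
#' @param days number of days (default 7).
#' @param seed integer seed, or `NULL`.
#' @param start_date first day.
#' @param nonwear_blocks optional data frame (`day`, `start_min`,
#'   `duration_min`) of device-off periods.
#' @return epoch data frame (`timestamp`, `axis1`-`axis3`, `vm`, `steps`).
#' @export
gen_accel_week <- function(steps_day, mvpa_min_day, light_min_day = 180,
                           days = 7, seed = NULL,
                           start_date = as.Date("2016-02-01"),
                           nonwear_blocks = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(steps_day >= 0, mvpa_min_day >= 0, light_min_day >= 0)
  day_min <- 1440
  if (mvpa_min_day + light_min_day >= day_min)
    stop("infeasible activity targets: active minutes exceed the day")
  pa <- (mvpa_min_day + light_min_day) / day_min
  q <- if (mvpa_min_day + light_min_day > 0)
    mvpa_min_day / (mvpa_min_day + light_min_day) else 0
  p_aa <- 0.75
  p_ia <- if (pa < 1) pa * (1 - p_aa) / (1 - pa) else 1
  # step cadences solving E[steps] = light*c_l + mvpa*c_m
  c_m <- 105
  c_l <- if (light_min_day > 0)
    (steps_day - mvpa_min_day * c_m) / light_min_day else 0
  if (c_l < 0) { c_l <- 0; c_m <- if (mvpa_min_day > 0) steps_day / mvpa_min_day else 0 }
  if (c_l > 60) { c_l <- 60
    c_m <- if (mvpa_min_day > 0) (steps_day - light_min_day * 60) / mvpa_min_day else 0 }
  u <- c(0.70, 0.55, 0.45) / sqrt(sum(c(0.70, 0.55, 0.45)^2))
  n <- days * day_min
  state <- integer(n)
  state[1] <- stats::rbinom(1, 1, pa)
  tr <- stats::runif(n)
  for (t in 2:n)
    state[t] <- if (state[t - 1] == 1) as.integer(tr[t] < p_aa)
                else as.integer(tr[t] < p_ia)
  hi <- state == 1 & stats::runif(n) < q          # MVPA minute
  lo <- state == 1 & !hi                          # light minute
  # in-state count levels keep a safety margin to the band edges so that
  # axis rounding cannot push an epoch across a cut-point
  vm <- numeric(n)
  vm[hi] <- pmin(30000, pmax(2700, stats::rlnorm(sum(hi), log(4200), 0.25)))
  vm[lo] <- pmin(2650, pmax(205, stats::rlnorm(sum(lo), log(800), 0.7)))
  sed <- !state
  nz <- sed & stats::runif(n) < 0.35
  vm[nz] <- pmin(195, pmax(1, stats::rlnorm(sum(nz), log(30), 1)))
  steps <- integer(n)
  steps[lo] <- stats::rpois(sum(lo), c_l)
  steps[hi] <- stats::rpois(sum(hi), c_m)
  ax <- round(outer(vm, u))
  if (!is.null(nonwear_blocks)) {
    for (r in seq_len(nrow(nonwear_blocks))) {
      b <- nonwear_blocks[r, ]
      idx <- (b$day - 1) * day_min + b$start_min + seq_len(b$duration_min)
      ax[idx, ] <- 0; steps[idx] <- 0L
    }
  }
  data.frame(
    timestamp = format(as.POSIXct(as.character(start_date), tz = "UTC") +
                         60 * (seq_len(n) - 1), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    axis1 = ax[, 1], axis2 = ax[, 2], axis3 = ax[, 3],
    vm = sqrt(rowSums(ax^2)), steps = steps
  )
}

#' Generate a 7-day diet recall around an isocaloric target
#'
#' Daily energy is lognormal around the target (mean-preserving;
#' `day_cv = 0` gives seven identical days) and the macro split is
#' jittered day-to-day inside the prescription bands (carbohydrate 55-60%,
#' protein 15-20%, fat 20-25% of energy), with grams back-computed at
#' Atwater factors.
#'
#' @param target_kcal prescribed daily energy.
#' @param macro_split list/vector with `cho`, `pro`, `fat` percentages
#'   summing to 100.
#' @param day_cv day-level coefficient of variation of energy.
#' @param days number of recall days.
#' @param seed integer seed, or `NULL`.
#' @param start_date first recall day.
#' @param constants an [eb_constants()] object.
#' @return data frame of recall days (`date`, grams, `energy_kcal`).
#' @export
gen_diet_week <- function(target_kcal,
                          macro_split = list(cho = 57.5, pro = 17.5, fat = 25),
                          day_cv = 0.06, days = 7, seed = NULL,
                          start_date = as.Date("2016-02-01"),
                          constants = eb_constants()) {
  if (!is.null(seed)) set.seed(seed)
  ms <- unlist(macro_split)
  stopifnot(abs(sum(ms) - 100) < 1e-6, target_kcal > 0, day_cv >= 0)
  sdlog <- sqrt(log(1 + day_cv^2))
  e <- target_kcal * exp(stats::rnorm(days, -sdlog^2 / 2, sdlog))
  pro <- rtrunc_norm(days, ms[["pro"]], if (day_cv > 0) 1 else 0, 15, 20)
  cho <- vapply(pro, function(p)
    rtrunc_norm(1, ms[["cho"]], if (day_cv > 0) 1 else 0,
                max(55, 75 - p), min(60, 80 - p)), 1)
  fat <- 100 - cho - pro
  atw <- constants$atwater
  data.frame(
    date = start_date + seq_len(days) - 1,
    protein_g = round(e * pro / 100 / atw[["protein"]], 1),
    carbohydrate_g = round(e * cho / 100 / atw[["carbohydrate"]], 1),
    fat_g = round(e * fat / 100 / atw[["fat"]], 1),
    energy_kcal = round(e, 1)
  )
}

#' Generate longitudinal outcome panels with known ground truth
#'
#' For each configured outcome, draws per-subject values at the three
#' assessment timepoints as group-timepoint means plus a subject-level
#' random intercept (inducing within-subject correlation `icc`, default
#' 0.7) plus independent residual noise, both scaled to the configured
#' per-timepoint SDs.  The default profile reproduces the emulated trial's
#' trajectory pattern: control drifts slightly (fat up, aerobic capacity
#' down), the training arm improves at both timepoints, and the
#' training-detraining arm improves then partially regresses while staying
#' above baseline.  A `"null"` profile gives every group the control
#' baseline distribution at all timepoints (no effects).
#'
#' @param cohort data frame from [gen_cohort()] (ids and groups).
#' @param config an [trial_config()] object.
#' @param seed integer seed, or `NULL`.
#' @param outcomes outcome names to generate (default: all configured);
#'   requesting an outcome missing from the profile errors.
#' @param profile `"table"` (configured trajectories) or `"null"`.
#' @return list with `panels` (named list of long data frames) and
#'   `manifest` (configured means and true change directions per group and
#'   outcome).
#' @export
gen_trajectories <- function(cohort, config = trial_config(), seed = NULL,
                             outcomes = names(config$outcomes),
                             profile = c("table", "null")) {
  profile <- match.arg(profile)
  if (!is.null(seed)) set.seed(seed)
  miss <- setdiff(outcomes, names(config$outcomes))
  if (length(miss)) stop("outcome(s) missing from effect profile: ",
                         paste(miss, collapse = ", "))
  tps <- config$design$timepoints
  icc <- config$design$icc
  panels <- list(); directions <- list()
  for (o in outcomes) {
    prof <- config$outcomes[[o]]
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      g <- cohort$group[i]
      p <- if (profile == "null") config$outcomes[[o]][["C"]] else prof[[g]]
      m <- if (profile == "null") rep(p$mean[1], length(tps)) else p$mean
      s <- if (profile == "null") rep(p$sd[1], length(tps)) else p$sd
      z_b <- stats::rnorm(1)                       # subject intercept
      z_w <- stats::rnorm(length(tps))             # occasion noise
      data.frame(subject_id = cohort$subject_id[i], group = g,
                 timepoint = tps,
                 value = m + s * (sqrt(icc) * z_b + sqrt(1 - icc) * z_w))
    })
    panels[[o]] <- do.call(rbind, rows)
    directions[[o]] <- vapply(names(prof), function(g)
      sign(prof[[g]]$mean[3] - prof[[g]]$mean[1]), 1)
  }
  list(panels = panels,
       manifest = list(profile = profile, icc = icc,
                       directions = directions,
                       means = lapply(config$outcomes[outcomes], identity)))
}

#' Simulate a complete three-arm trial
#'
#' Orchestrates the generators into a full in-silico trial: cohort,
#' monitored sessions for each training phase, a 7-day accelerometer week
#' and a 7-day diet recall per subject and assessment timepoint, and
#' longitudinal outcome panels.  All randomness flows from the single
#' `seed`; identical `(config, seed)` pairs give byte-identical outputs.
#' When `out_dir` is given, writes `subjects.csv`, `sessions.csv`,
#' `recalls.csv`, `outcomes.csv`, one `epochs_<id>_<timepoint>.csv` per
#' subject-timepoint, and `manifest.json` with the ground truth.
#'
#' @param config an [trial_config()] object.
#' @param seed integer seed.
#' @param out_dir output directory (created if needed), or `NULL` to
#'   return the objects only.
#' @param accel_days accelerometer days per assessment week.
#' @param constants an [eb_constants()] object.
#' @return (invisibly when writing) list with `cohort`, `sessions`,
#'   `recalls`, `epochs` (named list), `trajectories`, `manifest`.
#' @export
simulate_trial <- function(config = trial_config(), seed = 1, out_dir = NULL,
                           accel_days = 7, constants = eb_constants()) {
  set.seed(seed)
  cohort <- gen_cohort(config, seed = NULL, constants = constants)
  sessions <- do.call(rbind, lapply(1:4, function(p)
    gen_sessions(cohort, p, config, seed = NULL, constants = constants)))
  tps <- config$design$timepoints
  recalls <- list(); epochs <- list()
  for (ti in seq_along(tps)) {
    for (i in seq_len(nrow(cohort))) {
      g <- cohort$group[i]
      id <- cohort$subject_id[i]
      # subject-level targets follow the group trajectory proportionally
      st <- cohort$steps_day[i] * config$activity$steps[[g]][ti] /
        config$activity$steps[[g]][1]
      mv <- cohort$mvpa_min_day[i] * config$activity$mvpa_min[[g]][ti] /
        config$activity$mvpa_min[[g]][1]
      li <- config$activity$light_min[[g]][ti]
      ep <- gen_accel_week(st, mv, li, days = accel_days, seed = NULL,
                           start_date = as.Date("2016-02-01") + 140 * (ti - 1))
      epochs[[paste(id, tps[ti], sep = "_")]] <- ep
      rc <- gen_diet_week(cohort$ei_target_kcal[i] *
                            config$intake$ei_kcal[[g]][ti] /
                            config$intake$ei_kcal[[g]][1],
                          macro_split = config$intake$macro_split,
                          day_cv = config$intake$day_cv, seed = NULL,
                          start_date = as.Date("2016-02-01") + 140 * (ti - 1),
                          constants = constants)
      rc <- cbind(subject_id = id, timepoint = tps[ti], rc)
      recalls[[length(recalls) + 1]] <- rc
    }
  }
  recalls <- do.call(rbind, recalls)
  traj <- gen_trajectories(cohort, config, seed = NULL)
  manifest <- list(seed = seed, config_version = config$version,
                   groups = config$design$groups,
                   accel_days = accel_days,
                   ground_truth = traj$manifest)
  out <- list(cohort = cohort, sessions = sessions, recalls = recalls,
              epochs = epochs, trajectories = traj$panels,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "subjects.csv"), row.names = FALSE)
    utils::write.csv(sessions, file.path(out_dir, "sessions.csv"), row.names = FALSE)
    utils::write.csv(recalls, file.path(out_dir, "recalls.csv"), row.names = FALSE)
    long <- do.call(rbind, lapply(names(traj$panels), function(o)
      cbind(outcome = o, traj$panels[[o]])))
    utils::write.csv(long, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
    for (nm in names(epochs))
      utils::write.csv(epochs[[nm]],
                       file.path(out_dir, paste0("epochs_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
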