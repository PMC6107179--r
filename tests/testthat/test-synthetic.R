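small_cfg <- function() trial_config(overrides = list(
  design = list(groups = list(C = 4, TR = 3, TRD = 3))))

test_that("generators are deterministic in (config, seed)", {
  cfg <- small_cfg()
  c1 <- gen_cohort(cfg, seed = 7)
  c2 <- gen_cohort(cfg, seed = 7)
  expect_identical(c1, c2)
  expect_false(identical(c1, gen_cohort(cfg, seed = 8)))
  s1 <- gen_sessions(c1, 2, cfg, seed = 3)
  s2 <- gen_sessions(c1, 2, cfg, seed = 3)
  expect_identical(s1, s2)
  e1 <- gen_accel_week(6400, 35, seed = 5, days = 2)
  e2 <- gen_accel_week(6400, 35, seed = 5, days = 2)
  expect_identical(e1, e2)
  t1 <- gen_trajectories(c1, cfg, seed = 9)
  t2 <- gen_trajectories(c1, cfg, seed = 9)
  expect_identical(t1$panels, t2$panels)
})

test_that("cohort draws hit the configured baselines and inclusion window", {
  cfg <- trial_config(overrides = list(
    design = list(groups = list(C = 1000, TR = 1000, TRD = 1000))))
  co <- gen_cohort(cfg, seed = 101)
  for (g in c("C", "TR", "TRD")) {
    sub <- co[co$group == g, ]
    m <- cfg$outcomes$body_mass[[g]]
    expect_lt(abs(mean(sub$mass_kg) - m$mean[1]), 2 * m$sd[1] / sqrt(1000))
    bf <- cfg$outcomes$body_fat_pct[[g]]
    expect_lt(abs(mean(sub$body_fat_pct) - bf$mean[1]), 2 * bf$sd[1] / sqrt(1000))
    v <- cfg$outcomes$vo2max[[g]]
    expect_lt(abs(mean(sub$vo2max) - v$mean[1]), 2 * v$sd[1] / sqrt(1000))
  }
  expect_gte(mean(co$bmi >= 25.1 & co$bmi <= 34.9), 0.99)
  expect_equal(co$fat_mass_kg + co$ffm_kg, co$mass_kg)
  expect_equal(co$bmi, co$mass_kg / co$height_m^2)
  # RMR of the drawn resting gas exchange brackets the assessment range
  rmr <- weir_rmr(co$resting_vo2, co$resting_vco2)
  expect_equal(rmr, co$rmr_kcal, tolerance = 1e-9)
  for (g in c("C", "TR", "TRD"))
    expect_true(mean(rmr[co$group == g]) > 1300 &&
                  mean(rmr[co$group == g]) < 1800)
})

test_that("session draws keep lactate ordering and rise across phases 1-3", {
  cfg <- small_cfg()
  co <- gen_cohort(cfg, seed = 2)
  hr <- vo2 <- numeric(3)
  for (p in 1:3) {
    ss <- gen_sessions(co, p, cfg, seed = 30 + p)
    expect_true(all(ss$lactate_mid >= ss$lactate_pre))
    expect_true(all(ss$lactate_post >= ss$lactate_pre))
    expect_true(all(ss$mean_hr <= ss$max_hr))
    expect_true(all(ss$rpe >= 6 & ss$rpe <= 20))
    hr[p] <- mean(ss$mean_hr); vo2[p] <- mean(ss$mean_vo2_mlkgmin)
  }
  expect_false(is.unsorted(hr))
  expect_false(is.unsorted(vo2))
  # detraining arm generates no phase-4 sessions
  s4 <- gen_sessions(co, 4, cfg, seed = 44)
  expect_false(any(s4$group == "TRD"))
})

test_that("phase-1 lactates centre near their configured pre/post levels", {
  cfg <- trial_config(overrides = list(
    design = list(groups = list(C = 2, TR = 150, TRD = 150))))
  co <- gen_cohort(cfg, seed = 12)
  ss <- gen_sessions(co, 1, cfg, seed = 13)
  expect_lt(abs(mean(ss$lactate_pre) - 1.61), 0.15)
  expect_lt(abs(mean(ss$lactate_post) - 8.99), 0.3)
})

test_that("generated phase-2 sessions reproduce the session energy total", {
  cfg <- trial_config(overrides = list(
    design = list(groups = list(C = 2, TR = 250, TRD = 250))))
  co <- gen_cohort(cfg, seed = 3)
  ss <- gen_sessions(co, 2, cfg, seed = 4)
  se <- session_energy(ss, co)
  expect_lt(abs(mean(se$tee_kcal) - 326.8) / 326.8, 0.05)
})

test_that("accelerometer weeks are recovered by the analysis stage", {
  # round trip over replicate weeks: analyser recovers the generator's
  # step and MVPA targets within 10% on average
  steps <- mvpa <- numeric(12)
  for (i in 1:12) {
    ep <- gen_accel_week(6400, 35, 180, days = 3, seed = 500 + i)
    ds <- summarize_days(ep, 78)
    steps[i] <- mean(ds$steps); mvpa[i] <- mean(ds$mvpa_min)
  }
  expect_lt(abs(mean(steps) - 6400) / 6400, 0.10)
  expect_lt(abs(mean(mvpa) - 35) / 35, 0.10)
  # activity kilocalories land in the plausible daily range
  ep <- gen_accel_week(6400, 35, 180, days = 5, seed = 42)
  ds <- summarize_days(ep, 78)
  expect_true(mean(ds$activity_kcal) > 120 && mean(ds$activity_kcal) < 260)
  # zero-activity target yields an all-sedentary wear stream
  ep0 <- gen_accel_week(0, 0, 0, days = 1, seed = 1)
  expect_true(all(ep0$vm <= 199))
  expect_equal(sum(ep0$steps), 0)
  expect_error(gen_accel_week(100, 1200, 400), "infeasible")
})

test_that("inserted non-wear blocks are fully recovered", {
  blocks <- data.frame(day = c(1, 2), start_min = c(300, 600),
                       duration_min = c(120, 150))
  ep <- gen_accel_week(6400, 35, 180, days = 2, seed = 77,
                       nonwear_blocks = blocks)
  nw <- detect_nonwear(ep$vm)
  for (r in 1:2) {
    idx <- (blocks$day[r] - 1) * 1440 + blocks$start_min[r] +
      seq_len(blocks$duration_min[r])
    expect_true(all(nw[idx]))  # sensitivity 1 on block minutes
  }
})

test_that("diet weeks honour the target and pass the prescription check", {
  rc0 <- gen_diet_week(1840.5, day_cv = 0, seed = 1)
  expect_equal(nrow(unique(rc0[, -1])), 1)  # zero noise: identical days
  means <- vapply(1:40, function(i)
    mean_energy_intake(gen_diet_week(1840.5, seed = 600 + i))$energy_kcal_day, 1)
  expect_lt(abs(mean(means) - 1840.5) / 1840.5, 0.03)
  pass <- vapply(1:40, function(i) {
    s <- mean_energy_intake(gen_diet_week(1840.5, seed = 700 + i))
    all(prescription_check(s, target_kcal = 1840.5)$pass)
  }, TRUE)
  expect_gte(mean(pass), 0.95)
})

test_that("trajectory panels carry the configured effect structure", {
  cfg <- trial_config()
  co <- gen_cohort(cfg, seed = 21)
  tr <- gen_trajectories(co, cfg, seed = 22)
  expect_setequal(names(tr$panels), names(cfg$outcomes))
  expect_error(gen_trajectories(co, cfg, outcomes = "unknown_outcome"),
               "missing from effect profile")
  # TRD pattern for a positive-effect outcome: mid > post > baseline in the
  # configured means
  m <- cfg$outcomes$vo2max$TRD$mean
  expect_true(m[2] > m[3] && m[3] > m[1])
  # null profile: no group separation (interaction p far from 0)
  tn <- gen_trajectories(co, cfg, seed = 23, outcomes = "vo2max",
                         profile = "null")
  expect_equal(unique(tn$panels$vo2max$group[tn$panels$vo2max$subject_id == "C01"]),
               "C")
  # within-subject correlation is induced at roughly the configured ICC
  p <- tr$panels$body_mass
  wide <- reshape(p, idvar = "subject_id", timevar = "timepoint",
                  direction = "wide", drop = "group")
  cors <- cor(wide[, -1])
  expect_gt(mean(cors[upper.tri(cors)]), 0.45)
})

test_that("simulate_trial writes a complete, reproducible bundle", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "trial_a"); d2 <- file.path(tempdir(), "trial_b")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_trial(cfg, seed = 5, out_dir = d1, accel_days = 2)
  simulate_trial(cfg, seed = 5, out_dir = d2, accel_days = 2)
  for (f in c("subjects.csv", "sessions.csv", "recalls.csv", "outcomes.csv",
              "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  eps1 <- list.files(d1, pattern = "^epochs_")
  expect_length(eps1, 10 * 3)  # subjects x timepoints
  expect_identical(readLines(file.path(d1, eps1[1])),
                   readLines(file.path(d2, eps1[1])))
  unlink(c(d1, d2), recursive = TRUE)
})
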