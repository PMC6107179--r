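test_that("cut-point classifier matches the printed band edges", {
  expect_equal(as.character(classify_intensity(0)), "sedentary")
  expect_equal(as.character(classify_intensity(2689)), "light")
  expect_equal(as.character(classify_intensity(2690)), "moderate")
  expect_true(is_mvpa(2690))
  expect_false(is_mvpa(2689))
  expect_equal(as.character(classify_intensity(6167)), "vigorous")
  expect_equal(as.character(classify_intensity(99999)), "vigorous")
  expect_error(classify_intensity(-1), "nonnegative")
})

test_that("cut-point classifier equals exhaustive lookup on 0..20000", {
  vm <- 0:20000
  expect_identical(as.character(classify_intensity(vm)), oracle_band(vm))
})

test_that("non-wear detector handles the canonical cases", {
  expect_equal(sum(detect_nonwear(rep(50, 300))), 0)
  expect_equal(sum(detect_nonwear(rep(0, 120))), 120)
  # 45 zeros | 1-min spike | 45 zeros: spike tolerated, whole block non-wear
  v <- c(rep(0, 45), 50, rep(0, 45))
  expect_equal(sum(detect_nonwear(v)), 91)
  # 89-minute zero run stays wear
  expect_equal(sum(detect_nonwear(c(rep(0, 89), rep(100, 30)))), 0)
  # spike run longer than the tolerance breaks the block
  v2 <- c(rep(0, 60), rep(50, 3), rep(0, 60))
  expect_equal(sum(detect_nonwear(v2)), 0)
  # labelling is idempotent: relabelling a zeroed copy reproduces itself
  lab <- detect_nonwear(v)
  expect_identical(detect_nonwear(v), lab)
})

test_that("non-wear detector equals the O(n^2) oracle on random days", {
  set.seed(33)
  for (rep in 1:6) {
    # blocky stream: alternating zero and active runs of random lengths
    vm <- numeric(0)
    while (length(vm) < 1440) {
      vm <- c(vm, rep(0, sample(1:200, 1)),
              sample(c(rep(0:3, 3), 40, 500, 3000), sample(1:60, 1),
                     replace = TRUE))
    }
    vm <- vm[1:1440]
    expect_identical(detect_nonwear(vm), oracle_nonwear(vm))
  }
})

test_that("day summaries conserve wear time across bands", {
  ep <- gen_accel_week(6400, 35, 180, days = 1, seed = 21)
  ds <- summarize_day(ep, 80)
  expect_equal(ds$sedentary_min + ds$light_min + ds$moderate_min +
                 ds$vigorous_min, ds$wear_min)
  expect_equal(ds$mvpa_min, ds$moderate_min + ds$vigorous_min)
  # invariant to epoch order within the day (wear labels carried along)
  set.seed(5)
  perm <- sample(nrow(ep))
  ds2 <- summarize_day(ep[perm, ], 80, wear = rep(TRUE, nrow(ep)))
  ds1 <- summarize_day(ep, 80, wear = rep(TRUE, nrow(ep)))
  expect_equal(ds1$steps, ds2$steps)
  expect_equal(ds1$activity_kcal, ds2$activity_kcal)
  expect_equal(ds1$mvpa_min, ds2$mvpa_min)
})

test_that("per-epoch energy follows the gated count equation", {
  ep <- data.frame(timestamp = as.POSIXct("2016-02-01", tz = "UTC") + 60 * (0:1),
                   axis1 = c(2500, 1000), axis2 = 0, axis3 = 0, steps = 0)
  ds <- summarize_day(ep, 80, wear = c(TRUE, TRUE))
  expect_equal(ds$activity_kcal, 0.00094 * 2500 + 0.1346 * 80 - 7.37418,
               tolerance = 1e-9)
  # all-zero wear day: sedentary wear, no kcal, resting METs
  ep0 <- data.frame(timestamp = as.POSIXct("2016-02-01", tz = "UTC") + 60 * (0:99),
                    axis1 = 0, axis2 = 0, axis3 = 0, steps = 0)
  d0 <- summarize_day(ep0, 80, wear = rep(TRUE, 100))
  expect_equal(d0$steps, 0)
  expect_equal(d0$sedentary_min, 100)
  expect_equal(d0$activity_kcal, 0)
  expect_equal(d0$mean_mets, 1.0)
  # zero wear minutes flagged with undefined METs
  dz <- summarize_day(ep0, 80, wear = rep(FALSE, 100))
  expect_true(dz$zero_wear)
  expect_true(is.na(dz$mean_mets))
})

test_that("wear validity rule keeps >=4 days of >=600 minutes, inclusive", {
  mk <- function(wear) data.frame(wear_min = wear, steps = 0, partial = FALSE)
  v <- valid_wear_filter(mk(rep(800, 7)))
  expect_true(v$valid); expect_equal(nrow(v$days), 7)
  v2 <- valid_wear_filter(mk(c(700, 700, 700, 300, 300, 300, 300)))
  expect_false(v2$valid); expect_equal(nrow(v2$days), 3)
  v3 <- valid_wear_filter(mk(rep(600, 4)))
  expect_true(v3$valid)
  # partial boundary days are excluded from validity counting
  d <- mk(rep(800, 5)); d$partial <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  expect_false(valid_wear_filter(d)$valid)
})

test_that("epoch reader computes vm, validates counts and timestamps", {
  f <- tempfile(fileext = ".csv")
  ep <- data.frame(timestamp = format(as.POSIXct("2016-02-01", tz = "UTC") +
                                        60 * (0:9), "%Y-%m-%d %H:%M:%S"),
                   axis1 = 300, axis2 = 400, axis3 = 0, steps = 5)
  write.csv(ep, f, row.names = FALSE)
  r <- read_epoch_csv(f)
  expect_equal(r$vm, rep(500, 10))
  ep2 <- ep; ep2$axis1[4] <- -5
  write.csv(ep2, f, row.names = FALSE)
  expect_error(read_epoch_csv(f), "row 4")
  ep3 <- ep; ep3$timestamp[2] <- ep3$timestamp[1]
  write.csv(ep3, f, row.names = FALSE)
  expect_error(read_epoch_csv(f), "increasing")
  unlink(f)
})
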