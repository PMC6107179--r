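test_that("rm_anova matches the sums-of-squares oracle on small fixtures", {
  for (ns in list(c(4, 4, 4), c(5, 5, 5), c(5, 4, 3))) {
    p <- make_panel(ns, seed = sum(ns))
    r <- rm_anova(p, posthoc = FALSE)
    o <- oracle_split_plot(p)
    expect_equal(r$anova$F, o$F, tolerance = 1e-8)
    expect_equal(r$anova$df1, o$df1)
    expect_equal(r$anova$df2, o$df2)
  }
})

test_that("rm_anova degenerate and validation cases", {
  p <- make_panel(c(3, 3, 3))
  p$value <- 5
  r <- rm_anova(p)
  expect_equal(r$anova$F, rep(0, 3))
  expect_equal(r$anova$p, rep(1, 3))
  p1 <- make_panel(c(4, 4, 4))
  expect_error(rm_anova(p1[p1$group == "C", ]), "2 groups")
  expect_error(rm_anova(p1[p1$timepoint == "t1", ]), "2 timepoints")
  # incomplete subjects dropped with a logged count
  p2 <- make_panel(c(4, 4, 4))
  p2 <- p2[!(p2$subject_id == "s01" & p2$timepoint == "t3"), ]
  r2 <- rm_anova(p2, posthoc = FALSE)
  expect_equal(r2$n_dropped, 1)
  expect_equal(r2$n_subjects, 11)
})

test_that("Greenhouse-Geisser epsilon is bounded and applied conditionally", {
  p <- make_panel(c(6, 6, 6), seed = 3)
  r <- rm_anova(p, posthoc = FALSE)
  expect_true(r$gg_epsilon > 1 / 2 && r$gg_epsilon <= 1)
  ra <- rm_anova(p, gg = "always", posthoc = FALSE)
  expect_true(all(is.finite(ra$anova$p_corr[2:3])))
  expect_true(all(ra$anova$p_corr[2:3] >= 0 & ra$anova$p_corr[2:3] <= 1))
  expect_equal(ra$anova$df1_corr[2], ra$anova$df1[2] * ra$gg_epsilon)
  # strong sphericity violation triggers the conditional correction
  set.seed(8)
  grp <- rep(c("C", "TR", "TRD"), each = 10)
  id <- sprintf("v%02d", seq_along(grp))
  viol <- do.call(rbind, lapply(seq_along(id), function(i) {
    b <- rnorm(1)
    data.frame(subject_id = id[i], group = grp[i],
               timepoint = c("t1", "t2", "t3"),
               value = b + c(rnorm(1, 0, 0.05), rnorm(1, 0, 1), rnorm(1, 0, 6)))
  }))
  rv <- rm_anova(viol, posthoc = FALSE)
  expect_lt(rv$mauchly_p, 0.05)
  expect_true(rv$sphericity_corrected)
  expect_lt(rv$gg_epsilon, 0.9)
})

test_that("a built-in group-by-time effect is detected with high power", {
  # trial-sized design (21/14/14), training-arm slope of 1 total SD
  hits <- 0
  for (i in 1:60) {
    p <- make_panel(c(21, 14, 14), seed = 1000 + i, effect = 1.0)
    r <- rm_anova(p, posthoc = FALSE)
    hits <- hits + (r$anova$p[3] < 0.05)
  }
  expect_gte(hits / 60, 0.85)
})

test_that("Bonferroni adjustment caps and preserves order", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 3), 1.0)
  set.seed(2)
  p <- runif(20)
  adj <- bonferroni_adjust(p, m = 20)
  expect_true(all(adj >= p))
  expect_equal(order(adj[adj < 1]), order(p[adj < 1]))
  expect_error(bonferroni_adjust(1.2), "0, 1")
})

test_that("Hedges g matches hand arithmetic with its CI", {
  h0 <- hedges_g(10, 2, 14, 10, 2, 14)
  expect_equal(h0$g, 0)
  expect_equal(h0$ci_low, -h0$ci_high)
  h <- hedges_g(10, 2, 14, 12, 2, 14)
  expect_equal(round(h$g, 3), -0.971)
  expect_equal(h$g, -1 * (1 - 3 / 103))
  se <- sqrt(28 / 196 + h$g^2 / 52)
  expect_equal(h$ci_low, h$g - qnorm(0.975) * se)
  # antisymmetry and affine invariance of |g|
  set.seed(13)
  for (i in 1:10) {
    m <- rnorm(2, 20, 5); s <- runif(2, 1, 4); n <- sample(5:30, 2)
    a <- hedges_g(m[1], s[1], n[1], m[2], s[2], n[2])$g
    b <- hedges_g(m[2], s[2], n[2], m[1], s[1], n[1])$g
    expect_equal(a, -b)
    sc <- runif(1, 0.5, 3); sh <- rnorm(1)
    c <- hedges_g(sc * m[1] + sh, sc * s[1], n[1],
                  sc * m[2] + sh, sc * s[2], n[2])$g
    expect_equal(abs(c), abs(a))
  }
  expect_error(hedges_g(1, 0, 10, 2, 1, 10), "positive")
  expect_error(hedges_g(1, 1, 1, 2, 1, 10), "at least 2")
})

test_that("effect-size bands are exhaustive and non-overlapping", {
  expect_equal(interpret_es(0), "none")
  expect_equal(interpret_es(-0.61), "medium")
  expect_equal(interpret_es(0.85), "large")
  g <- seq(-3, 3, by = 0.001)
  bands <- interpret_es(g)
  expect_true(all(bands %in% c("none", "small", "medium", "large")))
  expect_equal(unname(table(bands)["none"]), sum(abs(g) < 0.2))
  expect_equal(unname(table(bands)["large"]), sum(abs(g) >= 0.8))
  # boundary values land in the upper band (closed lower edges)
  expect_equal(interpret_es(c(0.2, 0.5, 0.8)), c("small", "medium", "large"))
  expect_error(interpret_es(Inf), "finite")
})

test_that("ANCOVA adjustment reduces to raw means for balanced covariates", {
  p <- make_panel(c(4, 4, 4), seed = 5)
  # identical covariate sets in every group: cell covariate means equal,
  # so adjustment at the grand mean changes nothing
  cov <- data.frame(subject_id = sprintf("s%02d", 1:12),
                    kcal = rep(c(1700, 1800, 1900, 2000), 3))
  a <- ancova_adjust(p, cov)
  expect_equal(a$adjusted_means$adjusted_mean, a$adjusted_means$raw_mean,
               tolerance = 1e-9)
  expect_false(a$collinear)
})

test_that("ANCOVA adjusted means match the normal-equations oracle", {
  set.seed(19)
  p <- make_panel(c(5, 4, 3), seed = 23)
  cov <- data.frame(subject_id = unique(p$subject_id),
                    kcal = rnorm(12, 1800, 150),
                    steps = rnorm(12, 6400, 900))
  p$value <- p$value + 0.002 * cov$kcal[match(p$subject_id, cov$subject_id)]
  a <- ancova_adjust(p, cov)
  o <- oracle_ancova_means(p, cov)
  m <- merge(a$adjusted_means, o, by = c("group", "timepoint"))
  expect_equal(m$adjusted_mean.x, m$adjusted_mean.y, tolerance = 1e-8)
  # collinear covariates are flagged
  cov$steps <- 2 * cov$kcal
  expect_true(ancova_adjust(p, cov)$collinear)
})

test_that("percent change reproduces the reported gains", {
  expect_equal(round(percent_change(26.1, 33.1), 1), 26.8)
  expect_equal(round(percent_change(124.6, 158.5), 1), 27.2)
  expect_equal(percent_change(50, 50), 0)
  expect_error(percent_change(0, 10), "nonzero")
})
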