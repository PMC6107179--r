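# Independent oracles used by the equivalence tests.  These deliberately
# re-derive each quantity from first principles by a different route than
# the package implementation (explicit loops, textbook sums-of-squares,
# normal equations).

# Brute-force split-plot ANOVA via the classical sums-of-squares
# decomposition (group between, timepoint within, balanced within-subject).
oracle_split_plot <- function(panel) {
  panel$subject_id <- factor(panel$subject_id)
  panel$group <- factor(panel$group)
  panel$timepoint <- factor(panel$timepoint, levels = unique(panel$timepoint))
  k <- nlevels(panel$timepoint)
  g <- nlevels(panel$group)
  N <- nlevels(panel$subject_id)
  gm <- mean(panel$value)
  subj_mean <- tapply(panel$value, panel$subject_id, mean)
  subj_grp <- tapply(as.character(panel$group), panel$subject_id, function(x) x[1])
  grp_mean <- tapply(panel$value, panel$group, mean)
  tim_mean <- tapply(panel$value, panel$timepoint, mean)
  cell_mean <- tapply(panel$value, list(panel$group, panel$timepoint), mean)
  ng <- table(subj_grp)[levels(panel$group)]
  SS_group <- k * sum(ng * (grp_mean - gm)^2)
  SS_subj <- k * sum((subj_mean - grp_mean[subj_grp])^2)
  SS_time <- N * sum((tim_mean - gm)^2)
  SS_int <- 0
  for (gg in levels(panel$group)) for (tt in levels(panel$timepoint))
    SS_int <- SS_int + ng[gg] * (cell_mean[gg, tt] - grp_mean[gg] -
                                   tim_mean[tt] + gm)^2
  SS_tot <- sum((panel$value - gm)^2)
  SS_err <- SS_tot - SS_group - SS_subj - SS_time - SS_int
  df <- c(g - 1, N - g, k - 1, (g - 1) * (k - 1), (N - g) * (k - 1))
  MS <- c(SS_group, SS_subj, SS_time, SS_int, SS_err) / df
  data.frame(effect = c("group", "timepoint", "group:timepoint"),
             F = c(MS[1] / MS[2], MS[3] / MS[5], MS[4] / MS[5]),
             df1 = df[c(1, 3, 4)], df2 = df[c(2, 5, 5)])
}

# O(n^2) per-position non-wear scanner: a minute is non-wear iff the
# maximal run of "effectively zero" minutes containing it has length >=
# window, where a nonzero minute is effectively zero when it sits in a
# nonzero run of length <= tol flanked by >= flank zero minutes each side.
oracle_nonwear <- function(vm, window = 90, tol = 2, flank = 30) {
  n <- length(vm)
  effzero <- logical(n)
  for (i in seq_len(n)) {
    if (vm[i] == 0) { effzero[i] <- TRUE; next }
    a <- i; while (a > 1 && vm[a - 1] != 0) a <- a - 1
    b <- i; while (b < n && vm[b + 1] != 0) b <- b + 1
    if (b - a + 1 > tol) next
    zl <- 0; j <- a - 1
    while (j >= 1 && vm[j] == 0) { zl <- zl + 1; j <- j - 1 }
    zr <- 0; j <- b + 1
    while (j <= n && vm[j] == 0) { zr <- zr + 1; j <- j + 1 }
    effzero[i] <- zl >= flank && zr >= flank
  }
  out <- logical(n)
  for (i in seq_len(n)) {
    if (!effzero[i]) next
    a <- i; while (a > 1 && effzero[a - 1]) a <- a - 1
    b <- i; while (b < n && effzero[b + 1]) b <- b + 1
    out[i] <- (b - a + 1) >= window
  }
  out
}

# Exhaustive cut-point lookup, written as plain conditionals.
oracle_band <- function(vm) {
  vapply(vm, function(x) {
    if (x <= 199) "sedentary"
    else if (x <= 2689) "light"
    else if (x <= 6166) "moderate"
    else "vigorous"
  }, "")
}

# Normal-equations ANCOVA oracle: hand-built dummy design, beta solved by
# qr, adjusted cell means predicted at the covariate grand mean.
oracle_ancova_means <- function(panel, covariates) {
  dat <- merge(panel, covariates, by = "subject_id")
  covs <- setdiff(names(covariates), "subject_id")
  g <- factor(dat$group)
  t <- factor(dat$timepoint, levels = unique(dat$timepoint))
  X <- cbind(1, as.matrix(dat[covs]))
  for (lev in levels(g)[-1]) X <- cbind(X, as.numeric(g == lev))
  for (lev in levels(t)[-1]) X <- cbind(X, as.numeric(t == lev))
  for (lg in levels(g)[-1]) for (lt in levels(t)[-1])
    X <- cbind(X, as.numeric(g == lg & t == lt))
  beta <- qr.solve(crossprod(X), crossprod(X, dat$value))
  cells <- expand.grid(group = levels(g), timepoint = levels(t),
                       stringsAsFactors = FALSE)
  pred <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    x <- c(1, colMeans(dat[, covs, drop = FALSE]))
    for (lev in levels(g)[-1]) x <- c(x, as.numeric(cells$group[i] == lev))
    for (lev in levels(t)[-1]) x <- c(x, as.numeric(cells$timepoint[i] == lev))
    for (lg in levels(g)[-1]) for (lt in levels(t)[-1])
      x <- c(x, as.numeric(cells$group[i] == lg & cells$timepoint[i] == lt))
    pred[i] <- sum(x * beta)
  }
  cells$adjusted_mean <- pred
  cells
}

# Deterministic outcome panel used across the stats tests: unit total SD,
# compound-symmetric within-subject correlation `icc`, and an optional
# training-arm slope reaching `effect` total-SD units at the last timepoint.
make_panel <- function(ns = c(4, 4, 4), seed = 11, effect = 0, icc = 0.7) {
  set.seed(seed)
  grp <- rep(c("C", "TR", "TRD"), ns)
  id <- sprintf("s%02d", seq_along(grp))
  do.call(rbind, lapply(seq_along(id), function(i) {
    mu <- if (grp[i] == "TR") effect * c(0, 0.5, 1) else c(0, 0, 0)
    b <- stats::rnorm(1, 0, sqrt(icc))
    data.frame(subject_id = id[i], group = grp[i],
               timepoint = c("t1", "t2", "t3"),
               value = mu + b + stats::rnorm(3, 0, sqrt(1 - icc)))
  }))
}
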