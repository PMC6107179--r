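#' Mixed (split-plot) repeated-measures ANOVA for a trial outcome
#'
#' Analyses a long-format outcome panel (`subject_id`, `group`,
#' `timepoint`, `value`) with group as the between-subject factor and
#' timepoint as the within-subject factor, the design used for three-group,
#' three-timepoint training trials.  Subjects missing any timepoint are
#' dropped (complete-case) with the count recorded.  Sphericity of the
#' within factor is assessed with Mauchly's test; when violated (p below
#' `alpha_mauchly`, default 0.05) — or always, with `gg = "always"` — the
#' within-effect degrees of freedom and p-values are Greenhouse-Geisser
#' corrected.  The epsilon estimate comes from the pooled within-group
#' covariance of the repeated measures and lies in (1/(k-1), 1].
#'
#' Post-hoc comparisons cover all pairwise group differences within each
#' timepoint (two-sample pooled-variance t) and all pairwise timepoint
#' differences within each group (paired t), Bonferroni-adjusted with the
#' family size equal to the total number of comparisons.
#'
#' @param panel data frame with columns `subject_id`, `group`,
#'   `timepoint`, `value`.
#' @param gg `"conditional"` (default: correct only when Mauchly rejects),
#'   `"always"`, or `"never"`.
#' @param alpha_mauchly significance level for Mauchly's test.
#' @param posthoc run the Bonferroni post-hoc family (default `TRUE`).
#' @return an object of class `"eb_effect_report"`: list with `anova`
#'   (effect, df, F, p, corrected df/p), `mauchly_p`, `gg_epsilon`,
#'   `sphericity_corrected`, `posthoc`, `n_subjects`, `n_dropped`.
#' @export
rm_anova <- function(panel, gg = c("conditional", "always", "never"),
                     alpha_mauchly = 0.05, posthoc = TRUE) {
  gg <- match.arg(gg)
  panel <- as.data.frame(panel)
  need <- c("subject_id", "group", "timepoint", "value")
  stopifnot(all(need %in% names(panel)))
  panel$subject_id <- factor(panel$subject_id)
  panel$group <- droplevels(factor(panel$group))
  panel$timepoint <- droplevels(factor(panel$timepoint,
                                       levels = unique(panel$timepoint)))
  k <- nlevels(panel$timepoint)
  g <- nlevels(panel$group)
  if (g < 2) stop("need at least 2 groups")
  if (k < 2) stop("need at least 2 timepoints")

  # complete cases: one value per subject x timepoint
  tab <- table(panel$subject_id, panel$timepoint)
  if (any(tab > 1)) stop("duplicate subject x timepoint records")
  complete <- rownames(tab)[rowSums(tab) == k]
  n_dropped <- nlevels(panel$subject_id) - length(complete)
  panel <- droplevels(panel[panel$subject_id %in% complete, , drop = FALSE])
  if (any(table(panel$group) / k < 2))
    stop("need at least 2 complete subjects per group")
  n <- nlevels(panel$subject_id)

  eff_names <- c("group", "timepoint", "group:timepoint")
  if (stats::var(panel$value) == 0) {
    an <- data.frame(effect = eff_names,
                     df1 = c(g - 1, k - 1, (g - 1) * (k - 1)),
                     df2 = c(n - g, (n - g) * (k - 1), (n - g) * (k - 1)),
                     F = 0, p = 1, df1_corr = NA_real_, df2_corr = NA_real_,
                     p_corr = NA_real_)
    rep <- list(anova = an, mauchly_p = NA_real_, gg_epsilon = 1,
                sphericity_corrected = FALSE, posthoc = NULL,
                n_subjects = n, n_dropped = n_dropped)
    class(rep) <- "eb_effect_report"
    return(rep)
  }

  fit <- stats::aov(value ~ group * timepoint + Error(subject_id / timepoint),
                    data = panel)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject_id"]][[1]])
  within <- as.data.frame(sm[["Error: subject_id:timepoint"]][[1]])
  pick <- function(tbl, name) {
    i <- which(trimws(rownames(tbl)) == name)
    c(df = tbl$Df[i], F = tbl$`F value`[i], p = tbl$`Pr(>F)`[i])
  }
  b_grp <- pick(between, "group")
  w_tim <- pick(within, "timepoint")
  w_int <- pick(within, "group:timepoint")
  df_err_b <- between$Df[trimws(rownames(between)) == "Residuals"]
  df_err_w <- within$Df[trimws(rownames(within)) == "Residuals"]

  # wide matrix for sphericity diagnostics
  Y <- matrix(NA_real_, nrow = n, ncol = k,
              dimnames = list(levels(panel$subject_id), levels(panel$timepoint)))
  Y[cbind(as.integer(panel$subject_id), as.integer(panel$timepoint))] <- panel$value
  grp <- panel$group[match(rownames(Y), panel$subject_id)]

  eps <- gg_epsilon_matrix(Y, grp)
  mau_p <- tryCatch({
    mlm <- stats::lm(Y ~ grp)
    idata <- data.frame(timepoint = factor(colnames(Y), levels = colnames(Y)))
    stats::mauchly.test(mlm, X = ~1, idata = idata)$p.value
  }, error = function(e) NA_real_)

  correct <- switch(gg, always = TRUE, never = FALSE,
                    conditional = isTRUE(mau_p < alpha_mauchly))
  an <- data.frame(
    effect = eff_names,
    df1 = c(b_grp["df"], w_tim["df"], w_int["df"]),
    df2 = c(df_err_b, df_err_w, df_err_w),
    F = c(b_grp["F"], w_tim["F"], w_int["F"]),
    p = c(b_grp["p"], w_tim["p"], w_int["p"]),
    df1_corr = NA_real_, df2_corr = NA_real_, p_corr = NA_real_,
    row.names = NULL
  )
  if (correct) {
    wi <- an$effect != "group"
    an$df1_corr[wi] <- an$df1[wi] * eps
    an$df2_corr[wi] <- an$df2[wi] * eps
    an$p_corr[wi] <- stats::pf(an$F[wi], an$df1_corr[wi], an$df2_corr[wi],
                               lower.tail = FALSE)
  }

  ph <- if (posthoc) posthoc_bonferroni(panel) else NULL
  rep <- list(anova = an, mauchly_p = mau_p, gg_epsilon = eps,
              sphericity_corrected = correct, posthoc = ph,
              n_subjects = n, n_dropped = n_dropped)
  class(rep) <- "eb_effect_report"
  rep
}

#' @keywords internal
gg_epsilon_matrix <- function(Y, grp) {
  k <- ncol(Y)
  res <- Y - rowsum(Y, grp)[grp, , drop = FALSE] / c(table(grp))[grp]
  S <- crossprod(res) / (nrow(Y) - nlevels(grp))
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")  # orthonormal contrasts
  A <- t(C) %*% S %*% C
  eps <- sum(diag(A))^2 / ((k - 1) * sum(A^2))
  min(1, eps)
}

#' @keywords internal
posthoc_bonferroni <- function(panel) {
  groups <- levels(panel$group)
  times <- levels(panel$timepoint)
  rows <- list()
  for (tp in times) {
    sub <- panel[panel$timepoint == tp, ]
    for (i in seq_along(groups)) for (j in seq_along(groups)) if (i < j) {
      x <- sub$value[sub$group == groups[i]]
      y <- sub$value[sub$group == groups[j]]
      tt <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                     error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        family = "group_within_timepoint", timepoint = tp,
        contrast = paste(groups[i], "-", groups[j]),
        mean_diff = mean(x) - mean(y),
        p = if (is.null(tt)) NA_real_ else tt$p.value)
    }
  }
  for (gr in groups) {
    sub <- panel[panel$group == gr, ]
    wide <- stats::reshape(sub[, c("subject_id", "timepoint", "value")],
                           idvar = "subject_id", timevar = "timepoint",
                           direction = "wide")
    for (i in seq_along(times)) for (j in seq_along(times)) if (i < j) {
      x <- wide[[paste0("value.", times[i])]]
      y <- wide[[paste0("value.", times[j])]]
      tt <- tryCatch(stats::t.test(x, y, paired = TRUE),
                     error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        family = "timepoint_within_group", timepoint = gr,
        contrast = paste(times[i], "-", times[j]),
        mean_diff = mean(x - y),
        p = if (is.null(tt)) NA_real_ else tt$p.value)
    }
  }
  ph <- do.call(rbind, rows)
  ph$p_adj <- bonferroni_adjust(ph$p, m = nrow(ph))
  ph
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, m * p)` for each p-value; order-preserving and never below the
#' raw p-value.
#'
#' @param pvalues raw p-values in \[0, 1\].
#' @param m family size (default: number of p-values).
#' @return adjusted p-values.
#' @examples
#' bonferroni_adjust(c(0.01, 0.5), m = 3)  # 0.03, 1.0
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "bonferroni", n = max(m, length(pvalues)))
}

#' Bias-corrected Hedges' g with confidence interval
#'
#' Standardised mean difference `(mean1 - mean2) / s_p` with the pooled SD
#' using n-1 weights, multiplied by the small-sample correction
#' `J = 1 - 3 / (4(n1+n2) - 9)`.  The 95% CI uses
#' `SE^2 = (n1+n2)/(n1 n2) + g^2 / (2(n1+n2-2))`.
#' Antisymmetric in group order; `|g|` is invariant to a common affine
#' rescaling of both groups.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (`sd1 > 0`,
#'   `n1 >= 2`).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param conf confidence level.
#' @return list with `g`, `ci_low`, `ci_high`, `se`, `band` (from
#'   [interpret_es()]).
#' @examples
#' hedges_g(10, 2, 14, 12, 2, 14)$g  # -0.971
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2, conf = 0.95) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- (mean1 - mean2) / sp
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- d * J
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2 - 2)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(g = g, ci_low = g - z * se, ci_high = g + z * se, se = se,
       band = interpret_es(g))
}

#' Qualitative effect-size band
#'
#' Bands on `|g|`: none \[0, 0.2), small \[0.2, 0.5), medium \[0.5, 0.8),
#' large \[0.8, Inf) — exhaustive and non-overlapping.
#'
#' @param g finite effect-size value(s).
#' @return character vector of band labels.
#' @examples
#' interpret_es(c(0, -0.61, 0.85))
#' @export
interpret_es <- function(g) {
  if (any(!is.finite(g))) stop("effect sizes must be finite")
  a <- abs(g)
  ifelse(a < 0.2, "none",
         ifelse(a < 0.5, "small",
                ifelse(a < 0.8, "medium", "large")))
}

#' Covariate-adjusted group-by-time means (ANCOVA)
#'
#' Adjusts an outcome panel for per-subject covariates (e.g. daily energy
#' intake and steps/day) with a linear model in which the covariates enter
#' first, so the sequential F tests for group, timepoint and their
#' interaction are covariate-adjusted.  Adjusted cell means are model
#' predictions at the covariate grand means; when the covariates carry no
#' information (identical cell means by construction), adjusted means equal
#' raw means.
#'
#' @param panel outcome panel (`subject_id`, `group`, `timepoint`,
#'   `value`).
#' @param covariates data frame with `subject_id` and one or more numeric
#'   covariate columns (complete; one row per subject).
#' @return list with `adjusted_means` (group, timepoint, raw and adjusted
#'   mean), `anova` (sequential table with covariates first), `slopes`,
#'   `collinear` flag.
#' @export
ancova_adjust <- function(panel, covariates) {
  panel <- as.data.frame(panel)
  covariates <- as.data.frame(covariates)
  stopifnot("subject_id" %in% names(covariates))
  covs <- setdiff(names(covariates), "subject_id")
  if (!length(covs)) stop("no covariate columns supplied")
  if (anyNA(covariates[covs])) stop("covariates must be complete")
  dat <- merge(panel, covariates, by = "subject_id")
  if (nrow(dat) < nrow(panel)) stop("covariates missing for some subjects")
  dat$group <- factor(dat$group)
  dat$timepoint <- factor(dat$timepoint, levels = unique(dat$timepoint))

  collinear <- FALSE
  if (length(covs) > 1) {
    cm <- stats::cor(dat[covs])
    collinear <- any(abs(cm[upper.tri(cm)]) > 0.999)
  }
  fml <- stats::reformulate(c(covs, "group * timepoint"), response = "value")
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) collinear <- TRUE

  cells <- unique(dat[, c("group", "timepoint")])
  cells <- cells[order(cells$group, cells$timepoint), ]
  newd <- cells
  for (cv in covs) newd[[cv]] <- mean(dat[[cv]])
  cells$adjusted_mean <- stats::predict(fit, newdata = newd)
  raw <- stats::aggregate(value ~ group + timepoint, data = dat, FUN = mean)
  cells <- merge(cells, raw, by = c("group", "timepoint"))
  names(cells)[names(cells) == "value"] <- "raw_mean"
  list(adjusted_means = cells[order(cells$group, cells$timepoint), ],
       anova = stats::anova(fit),
       slopes = stats::coef(fit)[covs],
       collinear = collinear)
}

#' Percent change between two measurements
#'
#' `(post - pre) / pre * 100`; errors when `pre` is zero.
#'
#' @param pre,post measurements at the earlier and later occasion.
#' @return percent change.
#' @examples
#' percent_change(26.1, 33.1)  # +26.8
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("pre must be nonzero")
  (post - pre) / pre * 100
}

#' @export
print.eb_effect_report <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (", x$n_subjects, " complete subjects",
      if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped), ")\n", sep = "")
  cat(sprintf("Mauchly p = %.4g; GG epsilon = %.3f; correction %s\n",
              x$mauchly_p, x$gg_epsilon,
              if (x$sphericity_corrected) "applied" else "not applied"))
  print(x$anova, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("\nBonferroni post-hoc (family m =", nrow(x$posthoc), ")\n")
    print(utils::head(x$posthoc[x$posthoc$p_adj < 0.05, ], 12), row.names = FALSE)
  }
  invisible(x)
}
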