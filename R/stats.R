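# Group-level inference on normalized feature series: linear mixed-effects
# model of the post-ablation time course (animal as random intercept), ANOVA
# on the time and time-by-group fixed effects, per-timepoint two-group
# tests with a normality/variance-guided branch, and recovery-slope fits.

#' Fit the post-ablation mixed-effects model
#'
#' Models the feature value as a linear function of continuous time
#' (seconds), group, and their interaction, with a random intercept per
#' animal, restricted to `[t_from_s, t_to_s]` (default 30 s to 3 min, the
#' interval on which recovery slopes are compared). Fit by REML via
#' [lmerTest::lmer()]; ANOVA p-values (Satterthwaite) are reported for the
#' time and time-by-group effects.
#'
#' @param data Long tibble with columns `animal_id`, `group`, `t_rel_s` and
#'   the value column.
#' @param value Name of the value column (default `"normalized"`).
#' @param t_from_s,t_to_s Analysis interval in seconds post-ablation.
#' @return Object of class `"coi_lme"`: list with the `lmerMod` fit, an
#'   `anova` tibble, the fixed-effect table, random-intercept and residual
#'   variances, and a `singular` flag.
#' @export
fit_lme <- function(data, value = "normalized", t_from_s = 30,
                    t_to_s = 180) {
  stopifnot(all(c("animal_id", "group", "t_rel_s") %in% names(data)),
            value %in% names(data))
  d <- data[data$t_rel_s >= t_from_s & data$t_rel_s <= t_to_s &
              !is.na(data[[value]]), , drop = FALSE]
  d$.value <- d[[value]]
  d$group <- factor(d$group)
  if (length(unique(d$animal_id)) < 2) {
    stop("need at least 2 animals for a random-intercept model",
         call. = FALSE)
  }
  if (length(unique(d$t_rel_s)) < 2 || nlevels(d$group) < 2) {
    stop("need at least 2 timepoints and 2 groups in the interval",
         call. = FALSE)
  }
  fit <- lmerTest::lmer(
    .value ~ t_rel_s * group + (1 | animal_id), data = d, REML = TRUE,
    control = lme4::lmerControl(
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  )
  singular <- lme4::isSingular(fit)  # still reported, just not messaged
  an <- stats::anova(fit)   # Satterthwaite type III
  an_tbl <- tibble::tibble(
    term = rownames(an),
    statistic = an$`F value`,
    df = an$DenDF,
    p_value = an$`Pr(>F)`
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  fe <- summary(fit)$coefficients
  structure(
    list(
      fit = fit,
      fixed = tibble::tibble(term = rownames(fe),
                             estimate = fe[, "Estimate"],
                             std_error = fe[, "Std. Error"],
                             p_value = fe[, "Pr(>|t|)"]),
      anova = an_tbl,
      var_animal = vc$vcov[vc$grp == "animal_id"],
      var_residual = vc$vcov[vc$grp == "Residual"],
      p_time = an_tbl$p_value[an_tbl$term == "t_rel_s"],
      p_interaction = an_tbl$p_value[grepl(":", an_tbl$term)],
      singular = singular,
      interval = c(t_from_s, t_to_s),
      n_obs = nrow(d),
      n_animals = length(unique(d$animal_id)),
      groups = levels(d$group)
    ),
    class = "coi_lme"
  )
}

#' @exportS3Method base::print
print.coi_lme <- function(x, ...) {
  cat("Linear mixed-effects fit on [", x$interval[1], ",", x$interval[2],
      "] s:", x$n_obs, "obs,", x$n_animals, "animals, groups:",
      paste(x$groups, collapse = " vs "), "\n")
  if (x$singular) cat("  (singular fit: random-intercept variance at 0)\n")
  cat(sprintf("  ANOVA p(time) = %.3g, p(time x group) = %.3g\n",
              x$p_time, x$p_interaction))
  cat(sprintf("  var(animal) = %.4g, var(residual) = %.4g\n",
              x$var_animal, x$var_residual))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fixed effects of a [fit_lme()] result
#' @param x A `coi_lme` object.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms with estimates, standard errors and
#'   Satterthwaite p-values.
#' @export
tidy.coi_lme <- function(x, ...) x$fixed

#' One-row summary of a [fit_lme()] result
#' @param x A `coi_lme` object.
#' @param ... Unused.
#' @return One-row tibble: ANOVA p-values, variance components, fit size.
#' @export
glance.coi_lme <- function(x, ...) {
  tibble::tibble(
    p_time = x$p_time,
    p_interaction = x$p_interaction,
    var_animal = x$var_animal,
    var_residual = x$var_residual,
    singular = x$singular,
    n_obs = x$n_obs,
    n_animals = x$n_animals
  )
}

#' Two-group test at one timepoint
#'
#' Branch chosen from the data: Shapiro-Wilk normality on each group and a
#' median-centred Levene test of variance equality, all at `alpha`. Both
#' groups normal with equal variances: pooled two-sample t test; otherwise
#' Mann-Whitney (Wilcoxon rank-sum). The branch taken is reported.
#'
#' @param values_g1,values_g2 Numeric vectors (>= 3 values each).
#' @param alpha Significance level for the branch-choosing tests.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `normal_g1`,
#'   `normal_g2`, `equal_variance`, `n_g1`, `n_g2`.
#' @export
per_timepoint_test <- function(values_g1, values_g2, alpha = 0.05) {
  stopifnot(length(values_g1) >= 3, length(values_g2) >= 3)
  sw_p <- function(v) {
    if (length(unique(v)) == 1) return(0)  # degenerate: not normal
    stats::shapiro.test(v)$p.value
  }
  n1 <- sw_p(values_g1) > alpha
  n2 <- sw_p(values_g2) > alpha
  comb <- data.frame(
    v = c(values_g1, values_g2),
    g = factor(rep(c("g1", "g2"), c(length(values_g1), length(values_g2))))
  )
  if (length(unique(comb$v)) == 1) {
    # both samples a single shared constant: no evidence of any difference
    return(tibble::tibble(
      test = "mann-whitney", statistic = NA_real_, p_value = 1,
      normal_g1 = FALSE, normal_g2 = FALSE, equal_variance = TRUE,
      n_g1 = length(values_g1), n_g2 = length(values_g2)
    ))
  }
  ev <- if (length(unique(comb$v)) == 1) TRUE else {
    car::leveneTest(v ~ g, data = comb, center = stats::median)[1, "Pr(>F)"] >
      alpha
  }
  if (n1 && n2 && ev) {
    ht <- stats::t.test(values_g1, values_g2, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_g1, values_g2,
                                              exact = FALSE))
    test <- "mann-whitney"
  }
  tibble::tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    normal_g1 = n1, normal_g2 = n2, equal_variance = ev,
    n_g1 = length(values_g1), n_g2 = length(values_g2)
  )
}

#' Per-timepoint group comparison across a feature table
#'
#' Applies [per_timepoint_test()] at every timepoint shared by the two
#' groups (no multiple-testing correction: per-timepoint significance is
#' reported raw).
#'
#' @param features Normalized feature tibble (one `channel_band`).
#' @param group_col Column defining the two groups.
#' @param value Value column (default `"normalized"`).
#' @return Tibble: one row per `t_rel_s` with the test results.
#' @export
compare_timepoints <- function(features, group_col = "group",
                               value = "normalized") {
  g <- factor(features[[group_col]])
  stopifnot(nlevels(g) == 2)
  lv <- levels(g)
  features |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(.data$t_rel_s) |>
    dplyr::group_modify(function(df, key) {
      v1 <- df[[value]][df[[group_col]] == lv[1]]
      v2 <- df[[value]][df[[group_col]] == lv[2]]
      if (length(v1) < 3 || length(v2) < 3) return(tibble::tibble())
      per_timepoint_test(v1, v2)
    }) |>
    dplyr::ungroup()
}

#' Recovery slope of one series
#'
#' Ordinary least-squares slope of value against time over the valid points
#' in `[t_from_s, t_to_s]` (default 30 s to 3 min).
#'
#' @param t_rel_s,value Numeric vectors (times in seconds).
#' @param t_from_s,t_to_s Fit interval.
#' @return Slope in value units per second.
#' @export
recovery_slope <- function(t_rel_s, value, t_from_s = 30, t_to_s = 180) {
  keep <- !is.na(value) & t_rel_s >= t_from_s & t_rel_s <= t_to_s
  if (sum(keep) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(value[keep] ~ t_rel_s[keep]))[2])
}

#' Per-lesion recovery slopes of a feature table
#'
#' @param features Normalized feature tibble (one `channel_band`).
#' @param value Value column (default `"normalized"`).
#' @param t_from_s,t_to_s Fit interval in seconds.
#' @return Tibble: one row per lesion with its slope (per second).
#' @export
recovery_slopes <- function(features, value = "normalized",
                            t_from_s = 30, t_to_s = 180) {
  features |>
    dplyr::group_by(.data$lesion_id, .data$animal_id, .data$modality,
                    .data$transmural, .data$group) |>
    dplyr::summarise(
      slope_per_s = recovery_slope(.data$t_rel_s, .data[[value]],
                                   t_from_s, t_to_s),
      .groups = "drop"
    )
}

#' Simulate a long feature table directly from group trajectories
#'
#' Table-level cohort simulator used for statistical calibration
#' (type-I error, power, variance recovery) without synthesizing 1 kHz
#' signals: each lesion's value at each timepoint is its group trajectory
#' (or a supplied linear mean function) times a per-animal log-normal
#' amplitude factor, plus i.i.d. Gaussian measurement noise.
#'
#' @param mean_fun Named list of functions `group -> f(t)` giving the group
#'   mean trajectory.
#' @param n_per_group Named integer vector of lesions per group.
#' @param t_grid Timepoints in seconds.
#' @param sigma Measurement noise standard deviation.
#' @param n_animals Number of animals (round-robin assignment).
#' @param animal_sd Log-scale SD of the multiplicative animal factor.
#' @param seed Integer seed.
#' @return Long tibble: `lesion_id`, `animal_id`, `group`, `t_rel_s`,
#'   `normalized`.
#' @export
simulate_feature_table <- function(mean_fun, n_per_group,
                                   t_grid = seq(35, 175, by = 10),
                                   sigma = 0.05, n_animals = 5,
                                   animal_sd = 0, seed = 1L) {
  stopifnot(length(mean_fun) == length(n_per_group),
            all(names(n_per_group) %in% names(mean_fun)))
  set.seed(seed)
  amult <- exp(stats::rnorm(n_animals, 0, animal_sd))
  rows <- list()
  lesion <- 0L
  for (g in names(n_per_group)) {
    f <- mean_fun[[g]]
    for (i in seq_len(n_per_group[[g]])) {
      lesion <- lesion + 1L
      aid <- ((lesion - 1L) %% n_animals) + 1L
      rows[[lesion]] <- tibble::tibble(
        lesion_id = sprintf("L%03d", lesion),
        animal_id = paste0("A", aid),
        group = g,
        t_rel_s = t_grid,
        normalized = f(t_grid) * amult[aid] +
          stats::rnorm(length(t_grid), 0, sigma)
      )
    }
  }
  dplyr::bind_rows(rows)
}
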