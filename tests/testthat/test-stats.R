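lin_fun <- function(intercept, slope) {
  force(intercept); force(slope)
  function(t) intercept + slope * t
}

test_that("zero-noise linear data is fit exactly", {
  tab <- simulate_feature_table(
    mean_fun = list(A = lin_fun(1, -0.002), B = lin_fun(1, -0.0005)),
    n_per_group = c(A = 4, B = 4), sigma = 0, animal_sd = 0, seed = 1
  )
  fit <- fit_lme(tab)
  fe <- tidy(fit)
  expect_equal(unname(fe$estimate[fe$term == "t_rel_s"]), -0.002,
               tolerance = 1e-6)
  # group B slope = base + interaction
  int <- unname(fe$estimate[grepl(":", fe$term)])
  expect_equal(-0.002 + int, -0.0005, tolerance = 1e-6)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("per-timepoint test branches sensibly and is symmetric", {
  set.seed(5)
  # identical constant samples: no difference
  res <- per_timepoint_test(rep(1, 5), rep(1, 6))
  expect_equal(res$p_value, 1)
  # normal, equal variance: t branch; well-separated: significant
  x <- rnorm(10); y <- rnorm(10) + 3
  r1 <- per_timepoint_test(x, y)
  r2 <- per_timepoint_test(y, x)
  expect_equal(r1$test, "t")
  expect_lt(r1$p_value, 0.05)
  expect_equal(r1$p_value, r2$p_value)   # symmetric in its arguments
})

test_that("well-separated groups are detected across seeds", {
  hits <- 0L
  for (s in 1:40) {
    set.seed(s)
    r <- per_timepoint_test(rnorm(10), rnorm(10) + 3)
    hits <- hits + (r$p_value < 0.05)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("heavy-tailed data routes to the rank test", {
  picked <- vapply(1:40, function(s) {
    set.seed(s)
    per_timepoint_test(rcauchy(15), rcauchy(15))$test
  }, character(1))
  expect_gt(mean(picked == "mann-whitney"), 0.5)
})

test_that("recovery slope is the OLS slope on the analysis interval", {
  t <- seq(35, 175, by = 10)
  expect_equal(recovery_slope(t, 1 - 0.002 * t), -0.002, tolerance = 1e-10)
  expect_equal(recovery_slope(t, rep(0.7, length(t))), 0)
  # points outside [30, 180] are ignored
  t2 <- c(5, t, 400)
  v2 <- c(99, 1 - 0.002 * t, -99)
  expect_equal(recovery_slope(t2, v2), -0.002, tolerance = 1e-10)
  expect_true(is.na(recovery_slope(c(35, 45), c(NA, 1))))
})

test_that("nontransmural PFA lesions have steeper LF recovery slopes", {
  dynp <- group_dynamics("PFA_T+")$coi
  dynn <- group_dynamics("PFA_T-")$coi
  fplus <- function(t) coi_trajectory(t, dynp) / coi_trajectory(35, dynp)
  fminus <- function(t) coi_trajectory(t, dynn) / coi_trajectory(35, dynn)
  worse <- 0L
  for (s in 1:40) {
    tab <- simulate_feature_table(
      mean_fun = list(`T+` = fplus, `T-` = fminus),
      n_per_group = c(`T+` = 1, `T-` = 1), sigma = 0.03, seed = s
    )
    sl <- vapply(split(tab, tab$group), function(d) {
      recovery_slope(d$t_rel_s, d$normalized)
    }, numeric(1))
    worse <- worse + (sl[["T-"]] < sl[["T+"]])
  }
  expect_gte(worse / 40, 0.95)
})

test_that("the animal random-intercept variance is recovered on average", {
  # multiplicative log-normal animal effect, assessed on the log scale
  # where it is an additive intercept with variance animal_sd^2
  true_var <- 0.2^2
  est <- vapply(1:30, function(s) {
    tab <- simulate_feature_table(
      mean_fun = list(A = function(t) rep(2.0, length(t)),
                      B = function(t) rep(2.6, length(t))),
      n_per_group = c(A = 19, B = 19), sigma = 0.08,
      n_animals = 5, animal_sd = 0.2, seed = 1000 + s
    )
    tab$log_value <- log(tab$normalized)
    fit <- fit_lme(tab, value = "log_value")
    fit$var_animal
  }, numeric(1))
  expect_lt(abs(mean(est) - true_var) / true_var, 0.5)
})
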