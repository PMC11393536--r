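make_profiles <- function(n = 120, seed = 19) {
  derive_all(generate_cohort(gen_params(n_children = n, seed = seed)))
}

test_that("display routing follows skewness and variable type", {
  prof <- make_profiles(600, 19)
  s <- summarise_ler(prof, "whole_week")
  # near-symmetric variables -> mean path (timing means, evening %TDEI)
  expect_equal(s$T3$display, "mean_sd")
  expect_equal(s$E1a$display, "mean_sd")
  expect_equal(s$E2$display, "mean_sd")
  # right-skewed variables -> median path (evening main-meal time,
  # pre-bedtime %TDEI)
  expect_equal(s$T2$display, "median_iqr")
  expect_equal(s$E1b$display, "median_iqr")
  # count variable always median (IQR)
  expect_equal(s$F1$display, "median_iqr")
  # categorical variables report n (%) per bin with matching denominators
  expect_equal(sum(s$E1c1$categories$n), s$E1c1$n)
  expect_equal(sum(s$E1c1$categories$pct), 100, tolerance = 1e-9)
})

test_that("a heavily right-skewed evening-snack share takes the median path", {
  # a world of habitual snackers vs non-snackers with very variable snack
  # portions: small mean share keeps the ratio-of-sums from saturating, so
  # the right tail survives aggregation
  p <- gen_params(n_children = 600, seed = 19,
                  energy_shares = c(breakfast = 0.22, morning_snack = 0.08,
                                    lunch = 0.27, afternoon_snack = 0.09,
                                    dinner = 0.29, evening_snack = 0.05),
                  snack_child_sdlog = 1.2, snack_noise_sdlog = 1.0,
                  snack_heterogeneity = 1.5)
  s <- summarise_ler(derive_all(generate_cohort(p)), "whole_week")
  expect_gt(s$E3$skewness, 1)
  expect_equal(s$E3$display, "median_iqr")
})

test_that("summaries handle degenerate category distributions", {
  prof <- data.table::data.table(
    child_id = sprintf("c%02d", 1:50), stratum = factor("weekend",
      levels = c("whole_week", "weekdays", "weekend")),
    n_days = 1L, T1a = 0L, T1b = 0L, T2 = 1080, T3 = 1150,
    E1a = 35, E1b = 15, E1c1 = 1L, E1c2 = 0L, E2 = 28, E3 = 7,
    F1 = 2, F2 = 1L, F3 = 1L, missing_bedtime = FALSE, zero_tdei = FALSE)
  s <- summarise_ler(prof, "weekend")
  cats <- s$E1c1$categories
  expect_equal(cats$pct[cats$category == ">=1"], 100)
  expect_equal(cats$pct[cats$category == "0"], 0)
  expect_warning(summarise_ler(prof, "weekdays"), "empty stratum")
})

test_that("rare top bins are merged downward", {
  # 97 children with 0-2 days, 3 with 3 days (<4%) -> top bin merged
  x <- c(rep(0L, 40), rep(1L, 37), rep(2L, 20), rep(3L, 3))
  prof <- data.table::data.table(
    child_id = sprintf("c%03d", seq_along(x)),
    stratum = factor("whole_week",
                     levels = c("whole_week", "weekdays", "weekend")),
    n_days = 3L, T1a = x, T1b = x, T2 = 1080, T3 = 1150,
    E1a = 35, E1b = 15, E1c1 = x, E1c2 = x, E2 = 28, E3 = 7,
    F1 = 2, F2 = x, F3 = x, missing_bedtime = FALSE, zero_tdei = FALSE)
  s <- summarise_ler(prof, "whole_week")
  cats <- s$T1a$categories
  expect_equal(cats$category, c("0", "1", ">=2"))
  expect_equal(cats$n, c(40L, 37L, 23L))
})

test_that("week-weekend comparisons route tests by variable type", {
  prof <- make_profiles(150, 37)
  cmp <- compare_week_weekend(prof)
  expect_equal(cmp$test[cmp$variable == "T3"], "paired_t")
  expect_equal(cmp$test[cmp$variable == "F1"], "wilcoxon_signed_rank")
  expect_equal(cmp$test[cmp$variable == "F2"], "chi_square")
  expect_true(all(cmp$n_pairs <= length(unique(prof$child_id))))

  # identical strata -> t = 0, p = 1
  wd <- prof[prof$stratum == "weekdays", ]
  fake <- data.table::copy(wd)[, stratum := factor("weekend",
    levels = levels(wd$stratum))]
  cmp0 <- compare_week_weekend(rbind(wd, fake))
  expect_equal(cmp0$statistic[cmp0$variable == "T3"], 0)
  expect_equal(cmp0$p_value[cmp0$variable == "T3"], 1)

  # constant shift -> all signs equal, Wilcoxon flags it
  shifted <- data.table::copy(wd)[, stratum := factor("weekend",
    levels = levels(wd$stratum))][, F1 := F1 + 1]
  cmps <- compare_week_weekend(rbind(wd, shifted))
  expect_lt(cmps$p_value[cmps$variable == "F1"], 1e-6)
})

test_that("generator-imposed week/weekend E1b direction is recovered", {
  # weekday bedtimes sit closer to dinner, so pre-bedtime energy is larger
  # on weekdays in this world (as in the source cohort)
  prof <- make_profiles(400, 41)
  cmp <- compare_week_weekend(prof)
  d <- cmp$diff_means[cmp$variable == "E1b"]
  expect_gt(d, 0)
  expect_lt(cmp$p_value[cmp$variable == "E1b"], 0.01)
})

test_that("chi-square matches brute-force expected counts", {
  oracle <- function(tab) unname(suppressWarnings(
    chisq.test(tab, correct = FALSE)$statistic))
  set.seed(8)
  for (i in 1:25) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 30) + 1L, r, cc)
    got <- chi_square_from_table(tab)
    expect_equal(got$statistic, oracle(tab), tolerance = 1e-12)
    expect_equal(got$df, (r - 1) * (cc - 1))
  }
  expect_equal(chi_square_from_table(matrix(10, 2, 2))$statistic, 0)
  expect_error(chi_square_from_table(rbind(c(0, 0), c(5, 5))),
               "zero marginal")
})

test_that("spearman matrix is symmetric with flagged undefined cells", {
  prof <- make_profiles(200, 43)
  cm <- spearman_matrix(prof, "whole_week")
  expect_equal(cm$rho, t(cm$rho))
  expect_true(all(diag(cm$rho) == 1, na.rm = TRUE))
  expect_true(all(abs(cm$rho) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(length(cm$undefined), 0L)
  # x vs itself = 1 and x vs -x = -1 through the same code path
  expect_equal(cm$rho["T3", "T3"], 1)
  p2 <- data.table::copy(prof)[, E3 := -T3][]
  cm2 <- spearman_matrix(p2, "whole_week")
  expect_equal(cm2$rho["T3", "E3"], -1)
  # constant variable -> undefined, not silently zero
  p3 <- data.table::copy(prof)[, E2 := 5][]
  cm3 <- spearman_matrix(p3, "whole_week")
  expect_true("E2" %in% cm3$undefined)
  expect_true(all(is.na(cm3$rho["E2", ])))
  # later last occasions go with more post-bedtime eating in this world
  expect_gt(cm$rho["T3", "T1a"], 0.2)
})

test_that("sample-flow arithmetic reproduces the derived counts", {
  fl <- flow_counts(invited = 13146, completed = 7285, timed = 4869,
                    n_incomplete = 840, n_all_weekday = 644)
  expect_equal(round(fl$response_rate_pct, 1), 55.4)
  expect_equal(fl$n_whole_week, 4029)
  expect_equal(fl$n_week_weekend_overlap, 3385)

  coh <- generate_cohort(gen_params(n_children = 50, seed = 47))
  fl2 <- flow_counts(records = coh$records)
  expect_equal(fl2$timed, 50)
  expect_equal(fl2$n_whole_week, 50 - fl2$n_incomplete)
  prof <- derive_all(coh)
  expect_equal(fl2$n_whole_week, sum(prof$stratum == "whole_week"))
  expect_equal(fl2$n_weekdays_eligible, sum(prof$stratum == "weekdays"))
  expect_equal(fl2$n_weekend_eligible, sum(prof$stratum == "weekend"))

  empty <- flow_counts(records = mk_records(character(), integer(),
                                            character(), integer(),
                                            numeric()))
  expect_equal(empty$timed, 0L)
  expect_equal(empty$n_whole_week, 0L)
})
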