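## Synthetic diary cohorts.
##
## The generator states a world with the structure the derivation assumes:
## a trimodal eating-time density (breakfast / lunch / dinner peaks inside
## 06:00-09:59, 12:00-14:59, 17:00-18:29, with troughs approaching zero near
## 06:00, 12:00 and 17:00), optional per-daypart snacks, per-occasion energy
## shares summing to one before noise, usual bedtimes centred near 20:03
## (weekday) and 20:42 (weekend), 2 weekday + 1 weekend recorded days,
## sentinel time codes and child-wise missingness. Truth tables carry the
## generated per-child/per-day quantities so recovery can be tested without
## re-deriving them.

#' Generator parameters for a synthetic diary cohort
#'
#' Defaults are the stated world described above. Energy shares are mean
#' fractions of daily intake per occasion type and must sum to 1 before
#' noise; with the default snack probabilities they put roughly 36% of TDEI
#' after 17:00. Times are minutes since midnight.
#'
#' @param n_children number of children.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the parameters.
#' @param meal_time_means,meal_time_sds named (breakfast, lunch, dinner)
#'   truncated-normal time parameters, minutes.
#' @param snack_time_means,snack_time_sds named (morning, afternoon,
#'   evening) snack time parameters, minutes.
#' @param snack_probabilities per-daypart mean probability that a snack
#'   occasion occurs on a given day.
#' @param snack_heterogeneity Beta concentration of the child-level snack
#'   propensity around each daypart mean: per-day snack occurrence is
#'   Bernoulli with a child-specific probability drawn from
#'   `Beta(k p, k (1-p))`. Small `k` means habitual snackers and habitual
#'   non-snackers coexist, which over-disperses the day-count variables
#'   relative to a common binomial, as diary cohorts show.
#' @param snack_child_sdlog lognormal sd of a child-level multiplier on
#'   snack portion shares (families differ habitually in snack size);
#'   together with `snack_heterogeneity` this makes the evening-snack
#'   %TDEI distribution zero-inflated and right-skewed.
#' @param energy_shares named mean share of daily energy per occasion type
#'   (`breakfast`, `morning_snack`, `lunch`, `afternoon_snack`, `dinner`,
#'   `evening_snack`); must sum to 1.
#' @param share_noise_sdlog lognormal sd of the multiplicative noise applied
#'   to meal shares before renormalisation.
#' @param snack_noise_sdlog lognormal sd for snack shares; snacks are much
#'   more variable than meals, which makes the evening-snack %TDEI
#'   right-skewed as observed in diary data.
#' @param tdei_mean,tdei_sd daily energy intake, kcal.
#' @param bedtime_means named (weekday, weekend) usual bedtimes, minutes.
#' @param bedtime_sd child-level bedtime sd, minutes.
#' @param child_evening_sd sd of a child-level habitual shift applied to
#'   dinner and evening-snack times (families that eat late eat late on all
#'   days), minutes.
#' @param weekend_dinner_shift weekend dinner delay, minutes.
#' @param p_early_breakfast probability a day's breakfast comes from an
#'   early (06:30-centred) component, which keeps some intake in the
#'   06:00-06:29 half-hour bin.
#' @param p_missing_bedtime child-wise probability that both usual bedtimes
#'   are missing.
#' @param p_incomplete_days probability a child recorded fewer than 3 days
#'   (1 or 2, equally likely).
#' @param day_type_pattern day types of the up-to-3 recorded days.
#' @param p_no_time,p_unmatched per-record probabilities of the sentinel
#'   time codes 99 and 88.
#' @param lambda_extra_records Poisson mean of extra food records per
#'   occasion (several foods keyed at one recorded time).
#' @return an object of class `ler_gen_params`.
#' @export
gen_params <- function(n_children = 100L,
                       seed = 1L,
                       meal_time_means = c(breakfast = 480, lunch = 765,
                                           dinner = 1065),
                       meal_time_sds = c(breakfast = 30, lunch = 30,
                                         dinner = 30),
                       snack_time_means = c(morning = 660, afternoon = 900,
                                            evening = 1200),
                       snack_time_sds = c(morning = 20, afternoon = 25,
                                          evening = 40),
                       snack_probabilities = c(morning = 0.7,
                                               afternoon = 0.8,
                                               evening = 0.7),
                       snack_heterogeneity = 2,
                       snack_child_sdlog = 0.6,
                       energy_shares = c(breakfast = 0.21,
                                         morning_snack = 0.08,
                                         lunch = 0.26,
                                         afternoon_snack = 0.09,
                                         dinner = 0.27,
                                         evening_snack = 0.09),
                       share_noise_sdlog = 0.25,
                       snack_noise_sdlog = 0.6,
                       tdei_mean = 1650, tdei_sd = 250,
                       bedtime_means = c(weekday = 1203, weekend = 1242),
                       bedtime_sd = 25,
                       child_evening_sd = 20,
                       weekend_dinner_shift = 6,
                       p_early_breakfast = 0.10,
                       p_missing_bedtime = 0.18,
                       p_incomplete_days = 0.17,
                       day_type_pattern = c("weekday", "weekday", "weekend"),
                       p_no_time = 0.01,
                       p_unmatched = 0.005,
                       lambda_extra_records = 0.6) {
  p <- list(n_children = as.integer(n_children), seed = as.integer(seed),
            meal_time_means = meal_time_means, meal_time_sds = meal_time_sds,
            snack_time_means = snack_time_means,
            snack_time_sds = snack_time_sds,
            snack_probabilities = snack_probabilities,
            snack_heterogeneity = snack_heterogeneity,
            snack_child_sdlog = snack_child_sdlog,
            energy_shares = energy_shares,
            share_noise_sdlog = share_noise_sdlog,
            snack_noise_sdlog = snack_noise_sdlog,
            tdei_mean = tdei_mean, tdei_sd = tdei_sd,
            bedtime_means = bedtime_means, bedtime_sd = bedtime_sd,
            child_evening_sd = child_evening_sd,
            weekend_dinner_shift = weekend_dinner_shift,
            p_early_breakfast = p_early_breakfast,
            p_missing_bedtime = p_missing_bedtime,
            p_incomplete_days = p_incomplete_days,
            day_type_pattern = day_type_pattern,
            p_no_time = p_no_time, p_unmatched = p_unmatched,
            lambda_extra_records = lambda_extra_records)
  validate_gen_params(p)
  class(p) <- "ler_gen_params"
  p
}

validate_gen_params <- function(p) {
  if (is.na(p$n_children) || p$n_children < 1L) {
    stop("parameter error in field 'n_children': need a positive integer",
         call. = FALSE)
  }
  probs <- c(p$snack_probabilities, p$p_early_breakfast,
             p$p_missing_bedtime, p$p_incomplete_days, p$p_no_time,
             p$p_unmatched)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop("parameter error in field 'snack_probabilities'/'p_*': ",
         "probabilities must lie in [0,1]", call. = FALSE)
  }
  sds <- c(p$meal_time_sds, p$snack_time_sds, p$share_noise_sdlog,
           p$snack_noise_sdlog, p$snack_child_sdlog,
           p$snack_heterogeneity, p$tdei_sd, p$bedtime_sd)
  if (any(is.na(sds)) || any(sds <= 0)) {
    stop("parameter error in field 'meal_time_sds'/'snack_time_sds'/'*_sd': ",
         "scale parameters must be > 0", call. = FALSE)
  }
  need <- c("breakfast", "morning_snack", "lunch", "afternoon_snack",
            "dinner", "evening_snack")
  if (!all(need %in% names(p$energy_shares))) {
    stop("parameter error in field 'energy_shares': need names ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(p$energy_shares) - 1) > 1e-8) {
    stop("parameter error in field 'energy_shares': must sum to 1 ",
         "before noise", call. = FALSE)
  }
  if (!all(p$day_type_pattern %in% c("weekday", "weekend")) ||
      length(p$day_type_pattern) < 1L || length(p$day_type_pattern) > 3L) {
    stop("parameter error in field 'day_type_pattern': 1-3 entries of ",
         "weekday/weekend", call. = FALSE)
  }
  invisible(p)
}

#' Tuned parameters for night-eating threshold calibration
#'
#' A cohort parameterisation whose evening intake mirrors the population
#' the adopted NE criteria were calibrated on: dinner centred at 17:55
#' with a 28% mean dinner share, so the 75th percentile of the per-child
#' after-18:00 %TDEI falls near 30 (within the 27.5-32.5 rounding cell of
#' the 5-point criterion grid). Used to exercise
#' [calibrate_ne_threshold()] end-to-end.
#'
#' @inheritParams gen_params
#' @param ... further overrides passed to [gen_params()].
#' @return a `ler_gen_params`.
#' @export
gen_params_ne_calibration <- function(n_children = 2000L, seed = 1L, ...) {
  gen_params(n_children = n_children, seed = seed,
             meal_time_means = c(breakfast = 480, lunch = 765,
                                 dinner = 1075),
             energy_shares = c(breakfast = 0.21, morning_snack = 0.08,
                               lunch = 0.25, afternoon_snack = 0.10,
                               dinner = 0.28, evening_snack = 0.08),
             ...)
}

## exact truncated-normal sampler via inverse CDF (vectorised)
rtnorm <- function(n, mean, sd, lo, hi) {
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  qnorm(a + runif(n) * (b - a), mean, sd)
}

#' Generate a synthetic diary + bedtime cohort
#'
#' Deterministic for a fixed parameter set (including seed). Besides the
#' diary records and bedtime table, a `truth` component carries the
#' generated quantities (per-day TDEI, evening and after-18:00 energy, last
#' occasion time, dinner time; per-child true bedtimes and ratio-of-sums
#' evening share) computed before sentinel masking, for recovery tests.
#'
#' @param params a [gen_params()] object.
#' @return an object of class `ler_cohort`: list with elements `records`
#'   (diary record table as from [read_diary()]), `bedtimes`
#'   (as from [read_bedtimes()]; missing bedtimes are `NA`), `truth`
#'   (list of `children` and `days` data.tables) and `params`.
#' @examples
#' coh <- generate_cohort(gen_params(n_children = 5, seed = 7))
#' coh$truth$children
#' @export
generate_cohort <- function(params = gen_params()) {
  validate_gen_params(params)
  p <- params
  set.seed(p$seed)
  n <- p$n_children
  ids <- sprintf("c%05d", seq_len(n))

  ## --- children: bedtimes and habitual evening shift -----------------------
  bt_wd <- round(rnorm(n, p$bedtime_means[["weekday"]], p$bedtime_sd))
  bt_we <- round(bt_wd + (p$bedtime_means[["weekend"]] -
                            p$bedtime_means[["weekday"]]) +
                   rnorm(n, 0, p$bedtime_sd / 2))
  bt_wd <- pmin(pmax(bt_wd, 0L), 1439L)
  bt_we <- pmin(pmax(bt_we, 0L), 1439L)
  ev_shift <- rnorm(n, 0, p$child_evening_sd)
  ## habitual snacking: child-specific per-day snack probability (Beta
  ## around the daypart mean) and snack portion-size multiplier
  kk <- p$snack_heterogeneity
  snack_p <- vapply(c("morning", "afternoon", "evening"), function(dp) {
    pm <- min(max(p$snack_probabilities[[dp]], 0), 1)
    if (pm <= 0) rep(0, n) else if (pm >= 1) rep(1, n)
    else rbeta(n, kk * pm, kk * (1 - pm))
  }, numeric(n))
  snack_size <- exp(rnorm(n, 0, p$snack_child_sdlog))
  bt_missing <- runif(n) < p$p_missing_bedtime

  ## --- recorded days -------------------------------------------------------
  n_pat <- length(p$day_type_pattern)
  incomplete <- runif(n) < p$p_incomplete_days
  k_short <- sample(seq_len(max(1L, n_pat - 1L)), n, replace = TRUE)
  n_days <- ifelse(incomplete, k_short, n_pat)
  days <- data.table::data.table(
    child = rep(seq_len(n), n_days),
    day_index = unlist(lapply(n_days, seq_len), use.names = FALSE))
  days[, day_type := p$day_type_pattern[day_index]]
  nd <- nrow(days)

  ## --- occasions -----------------------------------------------------------
  types <- c("breakfast", "morning_snack", "lunch", "afternoon_snack",
             "dinner", "evening_snack")
  occ <- days[rep(seq_len(nd), each = length(types))]
  occ[, type := rep(types, nd)]
  dp_col <- c(morning_snack = 1L, afternoon_snack = 2L, evening_snack = 3L)
  pr <- rep(1, nrow(occ))
  sn <- occ$type %in% names(dp_col)
  pr[sn] <- snack_p[cbind(occ$child[sn], dp_col[occ$type[sn]])]
  occ <- occ[runif(nrow(occ)) < pr]
  no <- nrow(occ)

  ## occasion times: truncated normals inside daypart windows; dinner and
  ## evening snack share the child's habitual evening shift
  mu <- numeric(no); sg <- numeric(no); lo <- numeric(no); hi <- numeric(no)
  tt <- occ$type
  ch <- occ$child
  early <- tt == "breakfast" & runif(no) < p$p_early_breakfast
  mu[tt == "breakfast"] <- p$meal_time_means[["breakfast"]]
  mu[early] <- 390
  sg[tt == "breakfast"] <- p$meal_time_sds[["breakfast"]]
  sg[early] <- 20
  lo[tt == "breakfast"] <- 360; hi[tt == "breakfast"] <- 719
  m <- tt == "morning_snack"
  mu[m] <- p$snack_time_means[["morning"]]
  sg[m] <- p$snack_time_sds[["morning"]]; lo[m] <- 600; hi[m] <- 719
  m <- tt == "lunch"
  mu[m] <- p$meal_time_means[["lunch"]]
  sg[m] <- p$meal_time_sds[["lunch"]]; lo[m] <- 720; hi[m] <- 1019
  m <- tt == "afternoon_snack"
  mu[m] <- p$snack_time_means[["afternoon"]]
  sg[m] <- p$snack_time_sds[["afternoon"]]; lo[m] <- 720; hi[m] <- 1019
  m <- tt == "dinner"
  mu[m] <- p$meal_time_means[["dinner"]] + ev_shift[ch[m]] +
    ifelse(occ$day_type[m] == "weekend", p$weekend_dinner_shift, 0)
  sg[m] <- p$meal_time_sds[["dinner"]]; lo[m] <- 1020; hi[m] <- 1439
  m <- tt == "evening_snack"
  mu[m] <- p$snack_time_means[["evening"]] + ev_shift[ch[m]]
  sg[m] <- p$snack_time_sds[["evening"]]; lo[m] <- 1110; hi[m] <- 1439
  occ[, time := pmin(pmax(round(rtnorm(no, mu, sg, lo, hi)), lo), hi)]

  ## occasion energies: noisy shares renormalised per day, scaled by a
  ## truncated-normal daily intake, then rounded to whole kcal
  is_snack <- grepl("_snack$", occ$type)
  occ[, share := p$energy_shares[type] *
        ifelse(is_snack, snack_size[child], 1) *
        exp(rnorm(.N, 0, data.table::fifelse(is_snack,
                                             p$snack_noise_sdlog,
                                             p$share_noise_sdlog)))]
  occ[, share := share / sum(share), by = .(child, day_index)]
  day_tdei <- days[, .(child, day_index,
                       tdei_raw = rtnorm(nd, p$tdei_mean, p$tdei_sd,
                                         600, Inf))]
  occ <- day_tdei[occ, on = c("child", "day_index")]
  occ[, kcal := as.integer(round(share * tdei_raw))]

  ## --- split occasions into food records -----------------------------------
  n_rec <- 1L + rpois(no, p$lambda_extra_records)
  rec <- occ[rep(seq_len(no), n_rec)]
  rec[, occ_id := rep(seq_len(no), n_rec)]
  ## integer energy split that sums exactly to the occasion energy
  w <- runif(nrow(rec))
  rec[, w := w]
  rec[, kcal_rec := {
    if (.N == 1L) kcal[1L] else {
      cw <- cumsum(w / sum(w)) * kcal[1L]
      diff(c(0L, round(cw)))
    }
  }, by = occ_id]
  rec[, label := if (.N == 1L) type[1L] else paste0(type[1L], "_", seq_len(.N)),
      by = occ_id]

  ## --- sentinel masking ----------------------------------------------------
  u1 <- runif(nrow(rec)); u2 <- runif(nrow(rec))
  status <- rep("ok", nrow(rec))
  status[u1 < p$p_no_time] <- "no_time"
  status[u1 >= p$p_no_time & u2 < p$p_unmatched] <- "unmatched"
  records <- data.table::data.table(
    child_id = ids[rec$child],
    day_index = as.integer(rec$day_index),
    day_type = rec$day_type,
    clock_time = ifelse(status == "ok", as.integer(rec$time), NA_integer_),
    time_status = status,
    energy_kcal = as.numeric(rec$kcal_rec),
    label = rec$label)
  data.table::setorder(records, child_id, day_index, clock_time, na.last = TRUE)

  bedtimes <- data.table::data.table(
    child_id = ids,
    weekday_bedtime = ifelse(bt_missing, NA_integer_, as.integer(bt_wd)),
    weekend_bedtime = ifelse(bt_missing, NA_integer_, as.integer(bt_we)),
    source = "individual")

  ## --- truth (pre-masking) -------------------------------------------------
  occ[, kcal_occ := rec[, .(k = sum(kcal_rec)), by = occ_id]$k]
  truth_days <- occ[, .(
    day_type = day_type[1L],
    tdei = sum(kcal_occ),
    evening_kcal = sum(kcal_occ[time >= 1020]),
    after18_kcal = sum(kcal_occ[time >= 1080]),
    last_time = max(time),
    dinner_time = if (any(type == "dinner")) time[type == "dinner"][1L]
                  else NA_integer_,
    n_occasions = .N,
    n_evening_occasions = sum(time >= 1020)
  ), by = .(child, day_index)]
  truth_children <- truth_days[, .(
    n_days = .N,
    evening_share = 100 * sum(evening_kcal) / sum(tdei),
    after18_share = 100 * sum(after18_kcal) / sum(tdei),
    mean_last_time = mean(last_time)
  ), by = child]
  truth_children[, `:=`(child_id = ids[child],
                        true_weekday_bedtime = bt_wd[child],
                        true_weekend_bedtime = bt_we[child],
                        bedtime_missing = bt_missing[child])]
  truth_days[, child_id := ids[child]]
  truth_children[, child := NULL]
  truth_days[, child := NULL]
  data.table::setcolorder(truth_children, "child_id")
  data.table::setcolorder(truth_days, "child_id")

  out <- list(records = records[], bedtimes = bedtimes,
              truth = list(children = truth_children[], days = truth_days[]),
              params = p)
  class(out) <- "ler_cohort"
  out
}

#' @export
print.ler_cohort <- function(x, ...) {
  cat(sprintf("Synthetic LER cohort: %d children, %d records (seed %d)\n",
              x$params$n_children, nrow(x$records), x$params$seed))
  invisible(x)
}

#' Degrade exact times to historical meal-slot codes
#'
#' Replaces every exact clock time with the nominal coded time of its
#' historical meal slot (see [meal_slot_table()]), emulating the coarse
#' coding the electronic dataset held before exact times were keyed.
#' Sentinel rows are passed through unchanged. Note that the historical
#' scheme is not idempotent everywhere: the Tea and Evening-meal slots'
#' nominal times (17:00, 20:00) lie outside their own intervals, so
#' re-degrading already-coded data moves those records onward; the other
#' five slots' codes are fixed points.
#'
#' @param records record table.
#' @return record table with `clock_time` replaced by slot codes.
#' @export
degrade_to_slots <- function(records) {
  out <- data.table::copy(data.table::as.data.table(records))
  ok <- out$time_status == "ok"
  if (any(ok)) {
    out$clock_time[ok] <- code_meal_slot(out$clock_time[ok])$coded_time
  }
  out[]
}
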