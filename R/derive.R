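## Derivation of the 13 LER variables per child and day-type stratum.
##
## Strata: whole_week uses all 3 recorded days (children with fewer are
## ineligible, whatever the mix of day types); weekdays uses the weekday
## days of children with at least two of them; weekend uses the weekend
## days of children with at least one.
##
## Aggregation follows the two displayed rules exactly: timing variables
## are means of per-day minute values over the days where they exist, and
## every %TDEI variable is a ratio of sums across days (total window energy
## over total daily energy), never a mean of daily percentages.

LER_STRATA <- c("whole_week", "weekdays", "weekend")
LER_VARIABLES <- c("T1a", "T1b", "T2", "T3", "E1a", "E1b", "E1c1", "E1c2",
                   "E2", "E3", "F1", "F2", "F3")

#' Stratum eligibility for one child's recorded days
#'
#' @param days per-day rows for one child (needs a `day_type` column).
#' @return named list of integer row indices into `days` for each eligible
#'   stratum (`whole_week`, `weekdays`, `weekend`); ineligible strata are
#'   absent.
#' @export
stratify_days <- function(days) {
  n <- nrow(days)
  wd <- which(days$day_type == "weekday")
  we <- which(days$day_type == "weekend")
  out <- list()
  if (n == 3L) out$whole_week <- seq_len(n)
  if (length(wd) >= 2L) out$weekdays <- wd
  if (length(we) >= 1L) out$weekend <- we
  out
}

#' Derive timing variables (T1a, T1b, T2, T3) for one stratum
#'
#' T1a/T1b count recorded days with any occasion strictly after the
#' individual / population-average bedtime of that day's type. T2 is the
#' mean time of the evening main meal over days that have an evening
#' occasion (missing if none do); T3 the mean time of the day's last
#' occasion. Times in minutes. A missing individual bedtime makes T1a
#' missing.
#'
#' @param days [day_stats()] rows for one child's stratum days.
#' @param config a [ler_config()] (unused here, kept for a uniform
#'   signature).
#' @return named list with `T1a`, `T1b`, `T2`, `T3`.
#' @export
derive_timing <- function(days, config = ler_config()) {
  t1a <- if (any(is.na(days$after_bt_ind_any))) NA_integer_
         else sum(days$after_bt_ind_any)
  t1b <- sum(days$after_bt_avg_any)
  ev <- !is.na(days$ev_main_time)
  t2 <- if (any(ev)) mean(days$ev_main_time[ev]) else NA_real_
  lt <- days$last_time[!is.na(days$last_time)]
  t3 <- if (length(lt)) mean(lt) else NA_real_
  list(T1a = t1a, T1b = as.integer(t1b), T2 = t2, T3 = t3)
}

#' Derive energy variables (E1a, E1b, E2, E3) for one stratum
#'
#' Ratio-of-sums aggregation: each variable is 100 x (summed window energy
#' over the stratum days) / (summed TDEI). E1a covers the evening window,
#' E1b the inclusive window `[bedtime - ne2_width, bedtime]` per day-type
#' individual bedtime, E2 the evening main meals, E3 the evening snacks
#' (so E2 + E3 = E1a identically). Any stratum day with TDEI = 0 makes the
#' values missing and flags the child.
#'
#' @inheritParams derive_timing
#' @return named list with `E1a`, `E1b`, `E2`, `E3`, `zero_tdei`.
#' @export
derive_energy <- function(days, config = ler_config()) {
  if (any(days$tdei <= 0)) {
    return(list(E1a = NA_real_, E1b = NA_real_, E2 = NA_real_,
                E3 = NA_real_, zero_tdei = TRUE))
  }
  S <- sum(days$tdei)
  e1a <- 100 * sum(days$evening_kcal) / S
  e2 <- 100 * sum(days$ev_main_kcal) / S
  e3 <- e1a - e2
  e1b <- if (any(is.na(days$prebed_ind_kcal))) NA_real_
         else 100 * sum(days$prebed_ind_kcal) / S
  list(E1a = e1a, E1b = e1b, E2 = e2, E3 = e3, zero_tdei = FALSE)
}

#' Derive night-eating day counts (E1c1, E1c2) for one stratum
#'
#' Per-day evaluation with that day's own TDEI as denominator: E1c1 counts
#' days whose energy in `[ne1_start, 23:59]` reaches `ne1_criterion` %TDEI,
#' E1c2 days whose energy within the pre-bedtime window reaches
#' `ne2_criterion` %TDEI. The comparison is `>=` unless `ne_strict`.
#'
#' @inheritParams derive_timing
#' @return named list with `E1c1`, `E1c2` (day counts; `E1c2` missing when
#'   the individual bedtime is).
#' @export
derive_night_eating <- function(days, config = ler_config()) {
  if (any(days$tdei <= 0)) {
    return(list(E1c1 = NA_integer_, E1c2 = NA_integer_))
  }
  cmp <- if (config$ne_strict) `>` else `>=`
  e1c1 <- sum(cmp(100 * days$after_ne1_kcal / days$tdei,
                  config$ne1_criterion))
  e1c2 <- if (any(is.na(days$prebed_ind_kcal))) NA_integer_
          else sum(cmp(100 * days$prebed_ind_kcal / days$tdei,
                       config$ne2_criterion))
  list(E1c1 = as.integer(e1c1), E1c2 = as.integer(e1c2))
}

#' Derive meal-frequency variables (F1, F2, F3) for one stratum
#'
#' F1 is the median across stratum days of the number of evening
#' occasions (for 2-day strata the mean of the two values, as usual for a
#' median). F2 counts days with at least one occasion in the usual dinner
#' slot; F3 days with at least one evening occasion strictly after the
#' evening main meal.
#'
#' @inheritParams derive_timing
#' @return named list with `F1`, `F2`, `F3`.
#' @export
derive_frequency <- function(days, config = ler_config()) {
  list(F1 = stats::median(days$n_evening_occasions),
       F2 = as.integer(sum(days$dinner_slot_any)),
       F3 = as.integer(sum(days$post_main_any)))
}

#' Derive the 13 LER variables for every child and eligible stratum
#'
#' Runs [day_stats()] and applies [stratify_days()] and the four
#' `derive_*()` operations per child. Children are never silently dropped:
#' a child eligible for no stratum appears in the `excluded` attribute with
#' the reason.
#'
#' @param x a `ler_cohort` (from [generate_cohort()]), or a record table.
#' @param bedtimes bedtime table (ignored when `x` is a cohort).
#' @param config a [ler_config()].
#' @return a `data.table`, one row per child x eligible stratum, columns
#'   `child_id`, `stratum`, `n_days`, the 13 LER variables, and the flags
#'   `missing_bedtime` and `zero_tdei`. The attribute `excluded` lists
#'   children with no eligible stratum.
#' @export
derive_all <- function(x, bedtimes = NULL, config = ler_config()) {
  if (inherits(x, "ler_cohort")) {
    records <- x$records
    bedtimes <- x$bedtimes
  } else {
    records <- x
  }
  ds <- day_stats(records, bedtimes, config)
  by_child <- split(ds, by = "child_id", sorted = TRUE)
  rows <- vector("list", 3L * length(by_child))
  excluded <- character()
  k <- 0L
  for (child in names(by_child)) {
    days <- by_child[[child]]
    strata <- stratify_days(days)
    if (!length(strata)) {
      excluded <- c(excluded, child)
      next
    }
    cols <- as.list(days)
    for (s in names(strata)) {
      idx <- strata[[s]]
      ## plain column-list subset: the derive_*() operations only use `$`
      d <- lapply(cols, `[`, idx)
      tim <- derive_timing(d, config)
      ene <- derive_energy(d, config)
      ne <- derive_night_eating(d, config)
      fre <- derive_frequency(d, config)
      k <- k + 1L
      rows[[k]] <- list(
        child_id = child, stratum = s, n_days = length(idx),
        T1a = tim$T1a, T1b = tim$T1b, T2 = as.numeric(tim$T2),
        T3 = as.numeric(tim$T3),
        E1a = ene$E1a, E1b = ene$E1b, E1c1 = ne$E1c1, E1c2 = ne$E1c2,
        E2 = ene$E2, E3 = ene$E3,
        F1 = as.numeric(fre$F1), F2 = fre$F2, F3 = fre$F3,
        missing_bedtime = any(is.na(d$bt_ind)),
        zero_tdei = ene$zero_tdei)
    }
  }
  out <- if (k > 0L) data.table::rbindlist(rows[seq_len(k)]) else
    data.table::data.table(
      child_id = character(), stratum = character(), n_days = integer(),
      T1a = integer(), T1b = integer(), T2 = numeric(), T3 = numeric(),
      E1a = numeric(), E1b = numeric(), E1c1 = integer(),
      E1c2 = integer(), E2 = numeric(), E3 = numeric(), F1 = numeric(),
      F2 = integer(), F3 = integer(), missing_bedtime = logical(),
      zero_tdei = logical())
  out[, stratum := factor(stratum, levels = LER_STRATA)]
  data.table::setorder(out, child_id, stratum)
  data.table::setattr(out, "excluded", excluded)
  out[]
}

#' Bin a count variable into its stratum's reporting categories
#'
#' Day-count variables are reported as categories: 0/1/2/3 days for the
#' whole week, 0/1/>=2 for weekdays, 0/>=1 for weekend days.
#'
#' @param x integer day counts (NAs allowed).
#' @param stratum one of `"whole_week"`, `"weekdays"`, `"weekend"`.
#' @return factor with the stratum's category levels.
#' @export
bin_count_variable <- function(x, stratum = LER_STRATA) {
  stratum <- match.arg(stratum)
  switch(stratum,
    whole_week = factor(pmin(x, 3L), levels = 0:3,
                        labels = c("0", "1", "2", "3")),
    weekdays = factor(pmin(x, 2L), levels = 0:2,
                      labels = c("0", "1", ">=2")),
    weekend = factor(pmin(x, 1L), levels = 0:1,
                     labels = c("0", ">=1")))
}
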