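## Eating occasions and meal/snack classification.
##
## An eating occasion (EO) is every food/drink record sharing one recorded
## clock time within a child-day. Within each of the morning, afternoon and
## evening dayparts the largest-energy EO is the main meal (ties broken by
## earliest time); every other EO is a snack. EOs in the first-thing
## daypart (00:00-05:59) count toward daily energy but are never main meals.

#' Build eating occasions for one child-day
#'
#' Groups records by recorded clock time: one occasion per distinct
#' non-sentinel time, energy summed across constituent records, sorted
#' ascending. Sentinel-time records cannot be placed and are left out (their
#' energy is handled by the TDEI policy downstream).
#'
#' @param records record table for a single child-day.
#' @return a `data.table` with columns `child_id`, `day_index`,
#'   `clock_time`, `energy_kcal`, `n_records`. A day whose records are all
#'   sentinel yields an empty table with a warning.
#' @export
build_occasions <- function(records) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) {
    return(data.table::data.table(child_id = character(),
                                  day_index = integer(),
                                  clock_time = integer(),
                                  energy_kcal = numeric(),
                                  n_records = integer()))
  }
  if (data.table::uniqueN(records$child_id) > 1L ||
      data.table::uniqueN(records$day_index) > 1L) {
    stop("build_occasions expects records for a single child-day",
         call. = FALSE)
  }
  timed <- records[records$time_status == "ok"]
  if (nrow(timed) == 0L) {
    warning("child-day with only sentinel times: no occasions built",
            call. = FALSE)
    return(build_occasions(records[0L]))
  }
  occ <- timed[, .(energy_kcal = sum(energy_kcal), n_records = .N),
               by = .(child_id, day_index, clock_time)]
  data.table::setorder(occ, clock_time)
  occ[]
}

#' Assign dayparts and meal/snack roles to occasions
#'
#' Labels each occasion with its daypart and its role: within each of
#' morning, afternoon and evening the maximum-energy occasion is
#' `main_meal` (tie broken by earliest clock time), all others `snack`;
#' first-thing occasions are always snacks. The result is canonical
#' (sorted by time) and therefore invariant to input row order.
#'
#' @param occasions occasion table from [build_occasions()] (one child-day,
#'   or several -- roles are assigned within each child-day).
#' @param config a [ler_config()].
#' @return occasion table with added `daypart` and `role` columns.
#' @export
classify_roles <- function(occasions, config = ler_config()) {
  occ <- data.table::copy(data.table::as.data.table(occasions))
  if (nrow(occ) == 0L) {
    occ[, `:=`(daypart = factor(character(),
                                levels = c("first_thing", "morning",
                                           "afternoon", "evening")),
               role = character())]
    return(occ[])
  }
  data.table::setorder(occ, child_id, day_index, clock_time)
  occ[, daypart := daypart_of(clock_time, config$daypart_starts)]
  occ[, role := "snack"]
  occ[daypart != "first_thing",
      role := {
        r <- rep("snack", .N)
        r[which.max(energy_kcal)] <- "main_meal"  # ties: earliest time wins
        r
      },
      by = .(child_id, day_index, daypart)]
  occ[]
}

#' Detect main-meal skipping
#'
#' A meal is skipped on a day when no occasion falls inside its usual
#' mealtime slot (defaults: breakfast 06:00-09:59, lunch 12:00-14:59,
#' dinner 17:00-18:29). A day with dinner eaten only after 18:29 therefore
#' counts as a dinner-skipping day.
#'
#' @param occasions occasion table for one child-day (roles not required).
#' @param config a [ler_config()].
#' @return named logical vector `c(breakfast=, lunch=, dinner=)`, `TRUE`
#'   when skipped.
#' @export
detect_meal_skipping <- function(occasions, config = ler_config()) {
  t <- occasions$clock_time
  vapply(config$usual_slots, function(slot) {
    !any(t >= slot[1] & t <= slot[2])
  }, logical(1))
}

#' Per child-day profile statistics
#'
#' Computes, vectorised over the whole cohort, everything the LER
#' derivation needs per recorded day: TDEI under the sentinel-energy
#' policy, last occasion time, evening main-meal time and energy, energy in
#' the evening / after the NE1 time / within the pre-bedtime window, count
#' of evening occasions, dinner-slot and post-main-meal indicators, meal
#' skip flags and bedtime-relative indicators.
#'
#' @param records cohort record table.
#' @param bedtimes bedtime table (may omit children; their
#'   bedtime-dependent fields are `NA`).
#' @param config a [ler_config()].
#' @return a `data.table`, one row per child-day. Energy fields are kcal,
#'   times are minutes. `tdei` includes sentinel-record energy iff the
#'   `sentinel_energy` policy is `"include_in_tdei"`; `tdei_timed` never
#'   does.
#' @export
day_stats <- function(records, bedtimes = NULL, config = ler_config()) {
  rec <- data.table::as.data.table(records)
  ev_start <- config$daypart_starts[["evening"]]
  ne1 <- config$ne1_start
  dinner_slot <- config$usual_slots$dinner
  bslot <- config$usual_slots$breakfast
  lslot <- config$usual_slots$lunch

  occ <- rec[time_status == "ok",
             .(energy_kcal = sum(energy_kcal)),
             by = .(child_id, day_index, day_type, clock_time)]
  sent <- rec[time_status != "ok",
              .(sentinel_kcal = sum(energy_kcal)),
              by = .(child_id, day_index)]

  ds <- occ[, {
    e <- energy_kcal; t <- clock_time
    ev <- t >= ev_start
    ev_main_i <- if (any(ev)) {
      iv <- which(ev)
      iv[order(-e[iv], t[iv])][1L]   # largest energy, earliest on ties
    } else NA_integer_
    list(tdei_timed = sum(e),
         n_occasions = .N,
         n_evening_occasions = sum(ev),
         last_time = max(t),
         ev_main_time = if (is.na(ev_main_i)) NA_integer_ else t[ev_main_i],
         ev_main_kcal = if (is.na(ev_main_i)) 0 else e[ev_main_i],
         evening_kcal = sum(e[ev]),
         after_ne1_kcal = sum(e[t >= ne1]),
         dinner_slot_any = any(t >= dinner_slot[1] & t <= dinner_slot[2]),
         post_main_any = if (is.na(ev_main_i)) FALSE
                         else any(t > t[ev_main_i]),
         skip_breakfast = !any(t >= bslot[1] & t <= bslot[2]),
         skip_lunch = !any(t >= lslot[1] & t <= lslot[2]),
         skip_dinner = !any(t >= dinner_slot[1] & t <= dinner_slot[2]))
  }, by = .(child_id, day_index, day_type)]

  ## days whose records are all sentinel still exist as recorded days
  all_days <- unique(rec[, .(child_id, day_index, day_type)])
  ds <- ds[all_days, on = c("child_id", "day_index", "day_type")]
  for (col in c("tdei_timed", "n_occasions", "n_evening_occasions",
                "ev_main_kcal", "evening_kcal", "after_ne1_kcal")) {
    data.table::set(ds, which(is.na(ds[[col]])), col, 0)
  }
  for (col in c("dinner_slot_any", "post_main_any")) {
    data.table::set(ds, which(is.na(ds[[col]])), col, FALSE)
  }
  for (col in c("skip_breakfast", "skip_lunch", "skip_dinner")) {
    data.table::set(ds, which(is.na(ds[[col]])), col, TRUE)
  }

  ds <- sent[ds, on = c("child_id", "day_index")]
  ds[is.na(sentinel_kcal), sentinel_kcal := 0]
  ds[, tdei := tdei_timed +
       if (config$sentinel_energy == "include_in_tdei") sentinel_kcal else 0]

  ## bedtime-relative fields use the day-type's bedtime
  ds[, bt_avg := config$avg_bedtime[day_type]]
  if (!is.null(bedtimes)) {
    bt <- data.table::as.data.table(bedtimes)[
      , .(child_id, weekday_bedtime, weekend_bedtime)]
    ds <- bt[ds, on = "child_id"]
    ds[, bt_ind := data.table::fifelse(day_type == "weekend",
                                       as.numeric(weekend_bedtime),
                                       as.numeric(weekday_bedtime))]
    ds[, c("weekday_bedtime", "weekend_bedtime") := NULL]
  } else {
    ds[, bt_ind := NA_real_]
  }

  win <- occ[, .(child_id, day_index, clock_time, energy_kcal)]
  ds <- merge_window_energy(ds, win, "bt_ind", config$ne2_width,
                            "prebed_ind_kcal")
  ds <- merge_window_energy(ds, win, "bt_avg", config$ne2_width,
                            "prebed_avg_kcal")
  ds <- merge_after_flag(ds, win, "bt_ind", "after_bt_ind_any")
  ds <- merge_after_flag(ds, win, "bt_avg", "after_bt_avg_any")
  data.table::setorder(ds, child_id, day_index)
  ds[]
}

## energy inside [bt - width, bt], inclusive; NA when bedtime missing
merge_window_energy <- function(ds, occ, bt_col, width, out_col) {
  j <- occ[ds[, c("child_id", "day_index", bt_col), with = FALSE],
           on = c("child_id", "day_index"), allow.cartesian = TRUE]
  bt <- j[[bt_col]]
  inwin <- !is.na(bt) & !is.na(j$clock_time) &
    j$clock_time >= pmax(bt - width, 0) & j$clock_time <= bt
  j[, e := data.table::fifelse(inwin, energy_kcal, 0)]
  agg <- j[, .(v = if (all(is.na(.SD[[1L]]))) NA_real_ else sum(e)),
           by = .(child_id, day_index), .SDcols = bt_col]
  data.table::setnames(agg, "v", out_col)
  agg[ds, on = c("child_id", "day_index")]
}

## any occasion strictly after bedtime; NA when bedtime missing
merge_after_flag <- function(ds, occ, bt_col, out_col) {
  j <- occ[ds[, c("child_id", "day_index", bt_col), with = FALSE],
           on = c("child_id", "day_index"), allow.cartesian = TRUE]
  bt <- j[[bt_col]]
  j[, aft := !is.na(clock_time) & !is.na(bt) & clock_time > bt]
  agg <- j[, .(v = if (all(is.na(.SD[[1L]]))) NA else any(aft)),
           by = .(child_id, day_index), .SDcols = bt_col]
  data.table::setnames(agg, "v", out_col)
  agg[ds, on = c("child_id", "day_index")]
}
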