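## Definition-selection machinery: half-hour energy-intake profiling,
## daypart boundary inference from the profile's troughs, candidate-window
## quartile comparison, and calibration of the night-eating energy
## criterion from a percentile of the per-child window share.

#' Half-hour energy-intake profile
#'
#' For every child-day, the share of timed daily energy falling into each
#' of the 48 half-hour bins (so shares sum to 100 within each child-day);
#' bins are then averaged across child-days, optionally split by day type.
#' A bedtime density overlay (share of children whose day-type bedtime
#' falls in each bin) is attached when bedtimes are supplied.
#'
#' @param x a `ler_cohort` or a record table.
#' @param bedtimes optional bedtime table (taken from the cohort if `x` is
#'   one).
#' @param by_day_type logical; also compute weekday/weekend profiles.
#' @return an object of class `ler_ei_profile`: a list with `bins`
#'   (data.table: `bin_start`, `bin_end`, `mean_pct_tdei`, and per-day-type
#'   columns when requested), `n_child_days`, `bedtime_density`, and
#'   `share_sum_range` (range of the per-child-day share totals, which must
#'   be 100 up to rounding noise).
#' @export
compute_ei_profile <- function(x, bedtimes = NULL, by_day_type = TRUE) {
  if (inherits(x, "ler_cohort")) {
    records <- x$records
    if (is.null(bedtimes)) bedtimes <- x$bedtimes
  } else {
    records <- x
  }
  rec <- data.table::as.data.table(records)[time_status == "ok"]
  rec[, bin := clock_time %/% 30L]
  day_tot <- rec[, .(tot = sum(energy_kcal)), by = .(child_id, day_index)]
  day_tot <- day_tot[tot > 0]
  rec <- rec[day_tot, on = c("child_id", "day_index")]
  binned <- rec[, .(kcal = sum(energy_kcal)), by = .(child_id, day_index,
                                                     day_type, tot, bin)]
  binned[, share := 100 * kcal / tot]
  n_cd <- nrow(day_tot)
  grid <- data.table::data.table(bin = 0:47)
  overall <- binned[, .(s = sum(share)), by = bin]
  overall <- overall[grid, on = "bin"]
  overall[is.na(s), s := 0]
  bins <- data.table::data.table(bin_start = grid$bin * 30L,
                                 bin_end = grid$bin * 30L + 29L,
                                 mean_pct_tdei = overall$s / n_cd)
  if (by_day_type) {
    for (dt in c("weekday", "weekend")) {
      nd <- nrow(unique(binned[day_type == dt, .(child_id, day_index)]))
      v <- binned[day_type == dt, .(s = sum(share)), by = bin][grid, on = "bin"]
      v[is.na(s), s := 0]
      bins[, (paste0("mean_pct_tdei_", dt)) :=
             if (nd > 0) v$s / nd else NA_real_]
    }
  }
  bt_dens <- NULL
  if (!is.null(bedtimes)) {
    bt <- data.table::as.data.table(bedtimes)
    dens <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(rep(NA_real_, 48))
      tabulate(v %/% 30L + 1L, nbins = 48) / length(v) * 100
    }
    bt_dens <- data.table::data.table(
      bin_start = grid$bin * 30L,
      weekday_pct = dens(bt$weekday_bedtime),
      weekend_pct = dens(bt$weekend_bedtime))
  }
  ## invariant check material: per child-day shares must sum to 100
  sums <- binned[, .(s = sum(share)), by = .(child_id, day_index)]$s
  out <- list(bins = bins[], n_child_days = n_cd, bedtime_density = bt_dens,
              share_sum_range = if (length(sums)) range(sums)
                                else c(NA_real_, NA_real_))
  class(out) <- "ler_ei_profile"
  out
}

#' @export
print.ler_ei_profile <- function(x, ...) {
  top <- x$bins[order(-x$bins$mean_pct_tdei)][1:3]
  cat(sprintf("Half-hour EI profile over %d child-days\n", x$n_child_days))
  cat("  top bins:",
      paste(sprintf("%s (%.1f%%)", format_hhmm(top$bin_start),
                    top$mean_pct_tdei), collapse = ", "), "\n")
  invisible(x)
}

#' Infer daypart boundaries and usual meal slots from an EI profile
#'
#' Bins whose mean share reaches `epsilon` are "active"; maximal runs of
#' active bins form eating blocks. The three blocks with the largest total
#' mass are taken as the breakfast, lunch and dinner blocks, and each
#' daypart boundary is placed at the start of the first bin of its block --
#' i.e. at the end of the sub-epsilon trough that precedes the peak. The
#' usual meal slot around each peak is the maximal run of bins (within the
#' block) at or above `slot_frac` of the peak bin's height.
#'
#' @param profile a `ler_ei_profile`.
#' @param epsilon trough threshold, %TDEI per bin.
#' @param slot_frac fraction of peak height delimiting the usual slot.
#' @return list with `boundaries` (named minutes: morning, afternoon,
#'   evening), `usual_slots` (named list of inclusive minute ranges) and
#'   `blocks` (data.table of all active runs).
#' @export
infer_window_boundaries <- function(profile, epsilon = 0.5,
                                    slot_frac = 0.2) {
  v <- profile$bins$mean_pct_tdei
  start <- profile$bins$bin_start
  active <- v >= epsilon
  if (!any(active)) {
    stop("calibration error: profile has no bins above epsilon = ",
         epsilon, "; lower epsilon", call. = FALSE)
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- data.table::data.table(from = begins[r$values],
                                 to = ends[r$values])
  runs[, mass := vapply(seq_len(.N),
                        function(i) sum(v[runs$from[i]:runs$to[i]]),
                        numeric(1))]
  if (nrow(runs) < 3L) {
    stop("calibration error: found ", nrow(runs),
         " eating block(s), need 3 separated peaks; adjust epsilon",
         call. = FALSE)
  }
  main <- runs[order(-runs$mass)][1:3]
  main <- main[order(main$from)]
  boundaries <- c(morning = start[main$from[1]],
                  afternoon = start[main$from[2]],
                  evening = start[main$from[3]])
  slots <- vector("list", 3L)
  for (i in 1:3) {
    idx <- main$from[i]:main$to[i]
    pk <- idx[which.max(v[idx])]
    keep <- v[idx] >= slot_frac * v[pk]
    ## maximal run of above-threshold bins containing the peak
    rr <- rle(keep)
    re <- cumsum(rr$lengths); rb <- re - rr$lengths + 1L
    pos <- which(pk == idx)
    j <- which(rb <= pos & re >= pos)
    slots[[i]] <- c(start[idx[rb[j]]], start[idx[re[j]]] + 29L)
  }
  names(slots) <- c("breakfast", "lunch", "dinner")
  list(boundaries = boundaries, usual_slots = slots, blocks = runs[])
}

#' Per-child %TDEI for a candidate evening definition
#'
#' Candidates are either clock windows (`list(type = "after", start = m)`
#' giving energy in `[start, 23:59]`), the evening main meal
#' (`list(type = "main_meal")`), evening snacks (`list(type = "snacks")`),
#' or the pre-bedtime window (`list(type = "before_bed")`). Shares are
#' ratio-of-sums across each child's recorded days.
#'
#' @param x a `ler_cohort` or record table.
#' @param candidates named list of candidate descriptors (see above).
#' @param bedtimes optional bedtime table.
#' @param config a [ler_config()].
#' @param tol quartile tolerance (%TDEI) for flagging near-duplicates;
#'   defaults to `config$dup_tol`.
#' @return an object of class `ler_candidate_table`: data.table with one
#'   row per candidate (`candidate`, `q1`, `median`, `q3`, `n`) plus a
#'   `duplicate_of` column naming an earlier candidate whose three
#'   quartiles all lie within `tol`.
#' @export
compare_candidate_windows <- function(x, candidates = default_candidates(),
                                      bedtimes = NULL,
                                      config = ler_config(), tol = NULL) {
  if (inherits(x, "ler_cohort")) {
    records <- x$records
    if (is.null(bedtimes)) bedtimes <- x$bedtimes
  } else {
    records <- x
  }
  if (is.null(tol)) tol <- config$dup_tol
  rec <- data.table::as.data.table(records)[time_status == "ok"]
  ds <- day_stats(records, bedtimes, config)
  keep <- ds[, .(ok = all(tdei > 0)), by = child_id][ok == TRUE, child_id]
  ds <- ds[child_id %in% keep]
  tot <- ds[, .(S = sum(tdei)), by = child_id]

  share_for <- function(cand) {
    num <- switch(cand$type,
      after = {
        a <- rec[clock_time >= cand$start,
                 .(v = sum(energy_kcal)), by = child_id]
        a
      },
      main_meal = ds[, .(v = sum(ev_main_kcal)), by = child_id],
      snacks = ds[, .(v = sum(evening_kcal - ev_main_kcal)), by = child_id],
      before_bed = ds[, .(v = if (any(is.na(prebed_ind_kcal))) NA_real_
                              else sum(prebed_ind_kcal)), by = child_id],
      stop("unknown candidate type: ", cand$type, call. = FALSE))
    m <- num[tot, on = "child_id"]
    m[is.na(v) & cand$type != "before_bed", v := 0]
    100 * m$v / m$S
  }

  rows <- lapply(names(candidates), function(nm) {
    s <- share_for(candidates[[nm]])
    q <- stats::quantile(s, c(.25, .5, .75), na.rm = TRUE, names = FALSE)
    data.table::data.table(candidate = nm, q1 = q[1], median = q[2],
                           q3 = q[3], n = sum(!is.na(s)))
  })
  out <- data.table::rbindlist(rows)
  out[, duplicate_of := NA_character_]
  if (nrow(out) > 1L) {
    qm <- cbind(out$q1, out$median, out$q3)
    for (i in 2:nrow(out)) {
      for (j in 1:(i - 1L)) {
        if (all(abs(qm[i, ] - qm[j, ]) <= tol, na.rm = FALSE) %in% TRUE) {
          out$duplicate_of[i] <- out$candidate[j]
          break
        }
      }
    }
  }
  class(out) <- c("ler_candidate_table", class(out))
  out[]
}

#' Default candidate evening definitions
#'
#' The seven candidates compared when choosing the evening definitions:
#' energy after 16:00 / 17:00 / 18:00 / 19:00, the evening main meal,
#' evening snacks, and the 2-hour pre-bedtime window.
#' @return named list of candidate descriptors.
#' @export
default_candidates <- function() {
  list(after_16 = list(type = "after", start = 960L),
       after_17 = list(type = "after", start = 1020L),
       after_18 = list(type = "after", start = 1080L),
       after_19 = list(type = "after", start = 1140L),
       evening_main_meal = list(type = "main_meal"),
       evening_snacks = list(type = "snacks"),
       before_bed_2h = list(type = "before_bed"))
}

#' Calibrate the night-eating energy criterion
#'
#' Takes the configured percentile (default 75th) of the per-child
#' ratio-of-sums %TDEI in the candidate window, rounds it to the nearest
#' `rounding` percentage points, and accepts the resulting criterion iff
#' the implied prevalence -- the share of children meeting the criterion on
#' at least `prevalence_min_days` recorded day(s), each day judged against
#' its own TDEI -- falls inside the reference band.
#'
#' @param x a `ler_cohort` or record table.
#' @param window `list(type = "after", start = minutes)` or
#'   `list(type = "before_bed")`.
#' @param bedtimes optional bedtime table.
#' @param config a [ler_config()]; supplies percentile, rounding grid,
#'   band and comparison mode.
#' @return an object of class `ler_threshold_decision`: list with
#'   `window`, `percentile`, `raw_percentile_value`, `criterion` (%TDEI),
#'   `prevalence` (%), `band`, `accepted`, `n_children`.
#' @export
calibrate_ne_threshold <- function(x, window = list(type = "after",
                                                    start = 1080L),
                                   bedtimes = NULL, config = ler_config()) {
  if (inherits(x, "ler_cohort")) {
    records <- x$records
    if (is.null(bedtimes)) bedtimes <- x$bedtimes
  } else {
    records <- x
  }
  rec <- data.table::as.data.table(records)[time_status == "ok"]
  ds <- day_stats(records, bedtimes, config)
  keep <- ds[, .(ok = all(tdei > 0)), by = child_id][ok == TRUE, child_id]
  ds <- ds[child_id %in% keep]

  if (window$type == "after") {
    win <- rec[clock_time >= window$start,
               .(wkcal = sum(energy_kcal)), by = .(child_id, day_index)]
    ds <- win[ds, on = c("child_id", "day_index")]
    ds[is.na(wkcal), wkcal := 0]
  } else if (window$type == "before_bed") {
    ds[, wkcal := prebed_ind_kcal]
    ds <- ds[!is.na(wkcal)]
  } else {
    stop("unknown window type: ", window$type, call. = FALSE)
  }
  if (nrow(ds) == 0L || all(ds$wkcal == 0)) {
    stop("calibration error: no intake in the candidate window",
         call. = FALSE)
  }
  per_child <- ds[, .(share = 100 * sum(wkcal) / sum(tdei),
                      n_days = .N), by = child_id]
  raw <- stats::quantile(per_child$share, config$ne_percentile / 100,
                         names = FALSE)   # type 7: linear interpolation
  criterion <- round(raw / config$ne_rounding) * config$ne_rounding
  cmp <- if (config$ne_strict) `>` else `>=`
  day_hit <- ds[, .(n_hit = sum(cmp(100 * wkcal / tdei, criterion))),
                by = child_id]
  prevalence <- 100 * mean(day_hit$n_hit >= config$prevalence_min_days)
  out <- list(window = window,
              percentile = config$ne_percentile,
              raw_percentile_value = raw,
              criterion = criterion,
              prevalence = prevalence,
              band = config$ne_band,
              accepted = prevalence >= config$ne_band[1] &&
                prevalence <= config$ne_band[2],
              n_children = nrow(per_child))
  class(out) <- "ler_threshold_decision"
  out
}

#' @export
print.ler_threshold_decision <- function(x, ...) {
  w <- if (x$window$type == "after") {
    paste0("after ", format_hhmm(x$window$start))
  } else "2h before bedtime"
  cat(sprintf(
    "NE threshold decision (%s): p%g = %.2f%%TDEI -> criterion %g%%\n",
    w, x$percentile, x$raw_percentile_value, x$criterion))
  cat(sprintf("  implied prevalence %.1f%% vs band [%g, %g]: %s\n",
              x$prevalence, x$band[1], x$band[2],
              if (x$accepted) "accepted" else "not accepted"))
  invisible(x)
}
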