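# Straight-loop reference implementation of the 13 LER variables, written
# directly from the printed definitions (plain base R, one child at a time,
# no shared code with the package's vectorised path). Used as the
# independent oracle for equivalence testing.

oracle_derive_child <- function(rec, bt_wd, bt_we, config = ler_config()) {
  rec <- as.data.frame(rec)
  day_ids <- sort(unique(rec$day_index))
  days <- list()
  for (d in day_ids) {
    rd <- rec[rec$day_index == d, ]
    timed <- rd[rd$time_status == "ok", ]
    sentinel_kcal <- sum(rd$energy_kcal[rd$time_status != "ok"])
    times <- sort(unique(timed$clock_time))
    occ_t <- c(); occ_e <- c()
    for (t in times) {
      occ_t <- c(occ_t, t)
      occ_e <- c(occ_e, sum(timed$energy_kcal[timed$clock_time == t]))
    }
    ev <- which(occ_t >= 1020)
    main_i <- NA
    if (length(ev)) {
      best <- ev[1]
      for (i in ev) if (occ_e[i] > occ_e[best]) best <- i
      main_i <- best  # ties: earliest (first in ascending time order)
    }
    day_type <- rd$day_type[1]
    bt <- if (day_type == "weekend") bt_we else bt_wd
    bt_avg <- config$avg_bedtime[[day_type]]
    prebed <- NA
    if (!is.na(bt)) {
      prebed <- 0
      for (i in seq_along(occ_t)) {
        if (occ_t[i] >= max(bt - config$ne2_width, 0) && occ_t[i] <= bt) {
          prebed <- prebed + occ_e[i]
        }
      }
    }
    tdei <- sum(occ_e) +
      if (config$sentinel_energy == "include_in_tdei") sentinel_kcal else 0
    days[[length(days) + 1]] <- list(
      day_type = day_type,
      tdei = tdei,
      occ_t = occ_t, occ_e = occ_e, main_i = main_i,
      evening = sum(occ_e[occ_t >= 1020]),
      main_kcal = if (is.na(main_i)) 0 else occ_e[main_i],
      after18 = sum(occ_e[occ_t >= config$ne1_start]),
      prebed = prebed,
      after_bt = if (is.na(bt)) NA else any(occ_t > bt),
      after_bt_avg = any(occ_t > bt_avg),
      last = if (length(occ_t)) max(occ_t) else NA,
      main_t = if (is.na(main_i)) NA else occ_t[main_i],
      n_ev = length(ev),
      dinner_slot = any(occ_t >= config$usual_slots$dinner[1] &
                          occ_t <= config$usual_slots$dinner[2]),
      post_main = if (is.na(main_i)) FALSE else any(occ_t > occ_t[main_i]))
  }
  types <- vapply(days, function(d) d$day_type, "")
  strata <- list()
  if (length(days) == 3) strata$whole_week <- seq_along(days)
  if (sum(types == "weekday") >= 2) strata$weekdays <- which(types == "weekday")
  if (sum(types == "weekend") >= 1) strata$weekend <- which(types == "weekend")

  out <- list()
  for (s in names(strata)) {
    dd <- days[strata[[s]]]
    g <- function(f) vapply(dd, function(d) as.numeric(d[[f]]), numeric(1))
    tdei <- g("tdei")
    r <- list(child_id = rec$child_id[1], stratum = s,
              n_days = length(dd))
    ab <- g("after_bt")
    r$T1a <- if (any(is.na(ab))) NA else sum(ab)
    r$T1b <- sum(g("after_bt_avg"))
    mt <- g("main_t")
    r$T2 <- if (all(is.na(mt))) NA else mean(mt[!is.na(mt)])
    lt <- g("last")
    r$T3 <- if (all(is.na(lt))) NA else mean(lt[!is.na(lt)])
    if (any(tdei <= 0)) {
      r$E1a <- r$E1b <- r$E2 <- r$E3 <- NA
      r$E1c1 <- r$E1c2 <- NA
    } else {
      r$E1a <- 100 * sum(g("evening")) / sum(tdei)
      r$E2 <- 100 * sum(g("main_kcal")) / sum(tdei)
      r$E3 <- r$E1a - r$E2
      pb <- g("prebed")
      r$E1b <- if (any(is.na(pb))) NA else 100 * sum(pb) / sum(tdei)
      cmp <- if (config$ne_strict) `>` else `>=`
      r$E1c1 <- sum(cmp(100 * g("after18") / tdei, config$ne1_criterion))
      r$E1c2 <- if (any(is.na(pb))) NA
                else sum(cmp(100 * pb / tdei, config$ne2_criterion))
    }
    r$F1 <- median(g("n_ev"))
    r$F2 <- sum(g("dinner_slot"))
    r$F3 <- sum(g("post_main"))
    out[[s]] <- r
  }
  out
}

# oracle over a whole cohort -> data.frame comparable with derive_all()
oracle_derive <- function(records, bedtimes, config = ler_config()) {
  records <- as.data.frame(records)
  bedtimes <- as.data.frame(bedtimes)
  rows <- list()
  for (ch in sort(unique(records$child_id))) {
    b <- bedtimes[bedtimes$child_id == ch, ]
    bt_wd <- if (nrow(b)) b$weekday_bedtime[1] else NA
    bt_we <- if (nrow(b)) b$weekend_bedtime[1] else NA
    res <- oracle_derive_child(records[records$child_id == ch, ],
                               bt_wd, bt_we, config)
    for (r in res) rows[[length(rows) + 1]] <- as.data.frame(r)
  }
  do.call(rbind, rows)
}
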