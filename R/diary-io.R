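## Diary and bedtime I/O.
##
## A diary is long-format: one row per food/drink record with columns
## child_id, day_index, day_type, time, energy_kcal and optional label.
## Historically, exact times were not keyed; the electronic record held only
## a coarse meal-slot code (see meal_slot_table()). Exact times were keyed
## later, with two sentinel codes kept from that process:
##   99 -- the food was found but carried no recorded time;
##   88 -- a database food could not be matched back to the paper diary.

SENTINEL_NO_TIME <- "99"
SENTINEL_UNMATCHED <- "88"

#' Read a long-format food diary
#'
#' Parses one row per food/drink into a record table. Times are accepted as
#' `"HH:MM"` or 4-digit `"HHMM"`; the raw codes `99` and `88` become the
#' sentinel statuses `"no_time"` and `"unmatched"` with an `NA` clock time.
#' Any other unparseable or out-of-range time is a row-level error.
#'
#' @param path CSV file with columns `child_id`, `day_index`, `day_type`,
#'   `time`, `energy_kcal` and optionally `label`.
#' @return a `data.table` with columns `child_id` (character), `day_index`
#'   (integer), `day_type` (`"weekday"`/`"weekend"`), `clock_time` (integer
#'   minutes or `NA`), `time_status` (`"ok"`, `"no_time"`, `"unmatched"`),
#'   `energy_kcal` (double) and `label` (character).
#' @seealso [write_diary()], [read_bedtimes()], [validate_cohort()]
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, colClasses = list(character = "time"),
                           na.strings = c("", "NA"))
  need <- c("child_id", "day_index", "day_type", "time", "energy_kcal")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("diary format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as_records(data.frame(child_id = raw$child_id, day_index = raw$day_index,
                        day_type = raw$day_type, time = raw$time,
                        energy_kcal = raw$energy_kcal,
                        label = if ("label" %in% names(raw)) raw$label
                                else NA_character_))
}

#' Build a record table from raw columns
#'
#' The workhorse behind [read_diary()], usable directly on in-memory data.
#' Enforces the record invariants: `day_index` in 1-3, non-sentinel times in
#' 0-1439, non-negative energy.
#'
#' @param df data.frame with columns as in [read_diary()]; `time` is
#'   character (`"HH:MM"`/`"HHMM"` or the sentinel codes).
#' @return record `data.table` (see [read_diary()]).
#' @export
as_records <- function(df) {
  time_chr <- trimws(as.character(df$time))
  status <- rep("ok", nrow(df))
  status[is.na(time_chr) | time_chr == ""] <- "no_time"
  status[!is.na(time_chr) & time_chr == SENTINEL_NO_TIME] <- "no_time"
  status[!is.na(time_chr) & time_chr == SENTINEL_UNMATCHED] <- "unmatched"
  clock <- rep(NA_integer_, nrow(df))
  ok <- status == "ok"
  if (any(ok)) {
    parsed <- tryCatch(parse_hhmm(time_chr[ok]), error = function(e) e)
    if (inherits(parsed, "error")) {
      rows <- which(ok)[is.na(parse_hhmm_quiet(time_chr[ok]))]
      stop("diary row-level error: ", conditionMessage(parsed),
           if (length(rows)) paste0(" (row ",
                                    paste(head(rows, 5), collapse = ", "), ")"),
           call. = FALSE)
    }
    clock[ok] <- parsed
  }
  rec <- data.table::data.table(
    child_id = as.character(df$child_id),
    day_index = as.integer(df$day_index),
    day_type = as.character(df$day_type),
    clock_time = clock,
    time_status = status,
    energy_kcal = as.numeric(df$energy_kcal),
    label = if ("label" %in% names(df)) as.character(df$label)
            else NA_character_)
  ## day_index outside 1-3 is a cohort violation reported by
  ## validate_cohort(), not a read error; only structurally broken values
  ## are rejected here
  bad_day <- which(is.na(rec$day_index) | rec$day_index < 1L)
  if (length(bad_day)) {
    stop("diary row-level error: missing or non-positive day_index (row ",
         paste(head(bad_day, 5), collapse = ", "), ")", call. = FALSE)
  }
  bad_type <- which(!rec$day_type %in% c("weekday", "weekend"))
  if (length(bad_type)) {
    stop("diary row-level error: day_type must be weekday/weekend (row ",
         paste(head(bad_type, 5), collapse = ", "), ")", call. = FALSE)
  }
  bad_e <- which(is.na(rec$energy_kcal) | rec$energy_kcal < 0)
  if (length(bad_e)) {
    stop("diary row-level error: negative or missing energy (row ",
         paste(head(bad_e, 5), collapse = ", "), ")", call. = FALSE)
  }
  rec[]
}

## per-element parser returning NA instead of erroring, for row reporting
parse_hhmm_quiet <- function(x) {
  vapply(x, function(v) {
    tryCatch(parse_hhmm(v), error = function(e) NA_integer_)
  }, integer(1), USE.NAMES = FALSE)
}

#' Write a diary or bedtime table back to CSV
#'
#' Non-sentinel clock times round-trip bit-exactly through
#' `write_diary()`/[read_diary()]; sentinel rows are written with their raw
#' codes (`99`, `88`).
#'
#' @param records record table as returned by [read_diary()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(records, path) {
  time <- format_hhmm(records$clock_time)
  time[records$time_status == "no_time"] <- SENTINEL_NO_TIME
  time[records$time_status == "unmatched"] <- SENTINEL_UNMATCHED
  out <- data.frame(child_id = records$child_id,
                    day_index = records$day_index,
                    day_type = records$day_type,
                    time = time,
                    energy_kcal = records$energy_kcal,
                    label = records$label)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a per-child usual-bedtime table
#'
#' @param path CSV with columns `child_id`, `weekday_bedtime`,
#'   `weekend_bedtime` (`"HH:MM"`, blank = missing) and optionally `source`
#'   (`"individual"` or `"population_average"`).
#' @return a `data.table` with bedtimes as integer minutes.
#' @export
read_bedtimes <- function(path) {
  if (!file.exists(path)) stop("bedtime file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, na.strings = c("", "NA"),
                           colClasses = list(character =
                             c("weekday_bedtime", "weekend_bedtime")))
  need <- c("child_id", "weekday_bedtime", "weekend_bedtime")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("bedtime format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data.table::data.table(
    child_id = as.character(raw$child_id),
    weekday_bedtime = parse_hhmm(raw$weekday_bedtime),
    weekend_bedtime = parse_hhmm(raw$weekend_bedtime),
    source = if ("source" %in% names(raw)) as.character(raw$source)
             else "individual")
}

#' @rdname read_bedtimes
#' @param bedtimes bedtime table (minutes since midnight).
#' @export
write_bedtimes <- function(bedtimes, path) {
  out <- data.frame(child_id = bedtimes$child_id,
                    weekday_bedtime = format_hhmm(bedtimes$weekday_bedtime),
                    weekend_bedtime = format_hhmm(bedtimes$weekend_bedtime),
                    source = if ("source" %in% names(bedtimes))
                               bedtimes$source else "individual")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Historical meal-slot coding scheme
#'
#' The seven coarse meal slots used in the original electronic dietary
#' dataset, before exact times were keyed: each slot covers an inclusive
#' range of reported clock times and maps to a single nominal "original
#' time". For example a food consumed at 8:15 was entered as
#' "Breakfast, 0800".
#'
#' @return a `data.frame` with columns `slot_label`, `start`, `end`,
#'   `coded_time` (all times integer minutes).
#' @export
meal_slot_table <- function() {
  data.frame(
    slot_label = c("First thing", "Breakfast", "Mid-morning", "Lunch",
                   "Tea", "Evening meal", "Late evening"),
    start = c(0L, 420L, 600L, 720L, 870L, 1020L, 1170L),
    end = c(419L, 599L, 719L, 869L, 1019L, 1169L, 1439L),
    coded_time = c(360L, 480L, 660L, 780L, 1020L, 1200L, 1320L),
    stringsAsFactors = FALSE)
}

#' Code an exact clock time to its historical meal slot
#'
#' @param clock_time integer minutes since midnight, vectorised. Sentinel
#'   (`NA`) times cannot be coded and raise an error.
#' @return a `data.frame` with columns `slot_label` and `coded_time`
#'   (minutes). The seven slots partition the day, so every valid time maps
#'   to exactly one slot.
#' @examples
#' code_meal_slot(parse_hhmm("08:15"))  # Breakfast, 0800
#' @export
code_meal_slot <- function(clock_time) {
  if (any(is.na(clock_time))) {
    stop("cannot code sentinel/missing clock times to a meal slot",
         call. = FALSE)
  }
  clock_time <- as.integer(clock_time)
  if (any(clock_time < 0L | clock_time > 1439L)) {
    stop("clock_time outside 0-1439", call. = FALSE)
  }
  tab <- meal_slot_table()
  idx <- findInterval(clock_time, tab$start)
  data.frame(slot_label = tab$slot_label[idx],
             coded_time = tab$coded_time[idx],
             stringsAsFactors = FALSE)
}

#' Validate a diary + bedtime cohort
#'
#' Produces a report (never an error): sentinel counts, duplicate rows,
#' children with more than three day indices, and bedtime coverage.
#'
#' @param records record table ([read_diary()]).
#' @param bedtimes optional bedtime table ([read_bedtimes()]).
#' @return an object of class `ler_validation`: a list with `n_records`,
#'   `n_no_time`, `n_unmatched`, `n_children`, `day_counts` (per-child
#'   table), `bedtime_coverage`, and `violations` (data.frame of row
#'   references + rule).
#' @export
validate_cohort <- function(records, bedtimes = NULL) {
  dc <- records[, .(n_days = data.table::uniqueN(day_index)),
                by = child_id]
  viol <- list()
  too_many <- dc[dc$n_days > 3L, ]
  if (nrow(too_many)) {
    viol[[length(viol) + 1L]] <- data.frame(
      row = NA_integer_, child_id = too_many$child_id,
      rule = "more than 3 day indices")
  }
  bad_day <- which(records$day_index > 3L)
  if (length(bad_day)) {
    viol[[length(viol) + 1L]] <- data.frame(
      row = bad_day, child_id = records$child_id[bad_day],
      rule = "day_index outside 1-3")
  }
  key <- paste(records$child_id, records$day_index, records$clock_time,
               records$label, sep = "\r")
  dup <- which(duplicated(key) & records$time_status == "ok" &
                 !is.na(records$label))
  if (length(dup)) {
    viol[[length(viol) + 1L]] <- data.frame(
      row = dup, child_id = records$child_id[dup],
      rule = "duplicate (child, day, time, label) row")
  }
  mismatch <- records[, .(n = data.table::uniqueN(day_type)),
                      by = .(child_id, day_index)]
  mm <- mismatch[mismatch$n > 1L, ]
  if (nrow(mm)) {
    viol[[length(viol) + 1L]] <- data.frame(
      row = NA_integer_, child_id = mm$child_id,
      rule = "conflicting day_type within one day_index")
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(row = integer(), child_id = character(),
                    rule = character())
  cover <- NULL
  if (!is.null(bedtimes)) {
    kids <- unique(records$child_id)
    has_bt <- bedtimes$child_id[!is.na(bedtimes$weekday_bedtime) |
                                  !is.na(bedtimes$weekend_bedtime)]
    cover <- list(n_with_bedtime = sum(kids %in% has_bt),
                  n_without_bedtime = sum(!kids %in% has_bt))
  }
  out <- list(n_records = nrow(records),
              n_no_time = sum(records$time_status == "no_time"),
              n_unmatched = sum(records$time_status == "unmatched"),
              n_children = length(unique(records$child_id)),
              day_counts = as.data.frame(dc),
              bedtime_coverage = cover,
              violations = violations)
  class(out) <- "ler_validation"
  out
}

#' @export
print.ler_validation <- function(x, ...) {
  cat(sprintf("LER cohort validation: %d records, %d children\n",
              x$n_records, x$n_children))
  cat(sprintf("  sentinel times: %d no-time (99), %d unmatched (88)\n",
              x$n_no_time, x$n_unmatched))
  if (!is.null(x$bedtime_coverage)) {
    cat(sprintf("  bedtimes: %d with, %d without\n",
                x$bedtime_coverage$n_with_bedtime,
                x$bedtime_coverage$n_without_bedtime))
  }
  cat(sprintf("  violations: %d\n", nrow(x$violations)))
  invisible(x)
}
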