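#' Study configuration for LER derivation
#'
#' Collects every window boundary, threshold and policy switch used by the
#' pipeline. All times are integer minutes since midnight. Defaults encode
#' the adopted study definitions: dayparts first-thing 00:00-05:59, morning
#' 06:00-11:59, afternoon 12:00-16:59, evening 17:00-23:59; usual mealtime
#' slots breakfast 06:00-09:59, lunch 12:00-14:59, dinner 17:00-18:29;
#' night-eating criteria >=30 %TDEI after 18:00 (NE1) and >=25 %TDEI within
#' 2 h before bedtime (NE2); average bedtimes 20:03 (weekday) and 20:42
#' (weekend).
#'
#' @param daypart_starts named integer vector of daypart start minutes with
#'   names `first_thing`, `morning`, `afternoon`, `evening`.
#' @param usual_slots list of length-2 integer vectors (inclusive minute
#'   ranges) named `breakfast`, `lunch`, `dinner`.
#' @param ne1_start start minute of the NE1 window (window runs to 23:59).
#' @param ne1_criterion NE1 energy criterion, %TDEI.
#' @param ne2_width width of the pre-bedtime NE2/E1b window, minutes.
#' @param ne2_criterion NE2 energy criterion, %TDEI.
#' @param ne_strict logical; `FALSE` (default) uses `>=` for the NE
#'   criteria (the operational variable definitions), `TRUE` uses strict `>`.
#' @param avg_bedtime named integer vector, `weekday` and `weekend`
#'   population-average bedtimes (minutes).
#' @param sentinel_energy policy for energy on sentinel-time records:
#'   `"include_in_tdei"` (default; energy counts toward TDEI but toward no
#'   clock window) or `"exclude"`.
#' @param skew_threshold sample skewness above which a continuous variable
#'   is summarised as median (IQR) rather than mean (SD). The comparison is
#'   signed: the evening-intake variables this rule exists for are bounded
#'   below and their non-normality shows as a right tail, while mild left
#'   skew in timing means stays on the mean path.
#' @param rare_top_bin_pct percentage below which the top count bin is
#'   merged with the one beneath it when tabulating categorical variables.
#' @param profile_epsilon trough threshold (%TDEI per half-hour bin) used
#'   when inferring daypart boundaries from an EI profile.
#' @param slot_frac fraction of a peak's height used to delimit the usual
#'   mealtime slot around that peak.
#' @param dup_tol quartile tolerance (%TDEI) for flagging near-duplicate
#'   candidate windows.
#' @param ne_percentile percentile of per-child window %TDEI used to set
#'   the NE energy criterion.
#' @param ne_rounding criterion rounding grid, percentage points.
#' @param ne_band length-2 reference prevalence band (%) a calibrated
#'   criterion is accepted against.
#' @param prevalence_min_days minimum number of qualifying days for a child
#'   to count toward the implied NE prevalence.
#' @return an object of class `ler_config` (a validated named list).
#' @examples
#' cfg <- ler_config()
#' cfg$usual_slots$dinner
#' @export
ler_config <- function(daypart_starts = c(first_thing = 0L, morning = 360L,
                                          afternoon = 720L, evening = 1020L),
                       usual_slots = list(breakfast = c(360L, 599L),
                                          lunch = c(720L, 899L),
                                          dinner = c(1020L, 1109L)),
                       ne1_start = 1080L,
                       ne1_criterion = 30,
                       ne2_width = 120L,
                       ne2_criterion = 25,
                       ne_strict = FALSE,
                       avg_bedtime = c(weekday = 1203L, weekend = 1242L),
                       sentinel_energy = c("include_in_tdei", "exclude"),
                       skew_threshold = 0.5,
                       rare_top_bin_pct = 4,
                       profile_epsilon = 0.5,
                       slot_frac = 0.2,
                       dup_tol = 1,
                       ne_percentile = 75,
                       ne_rounding = 5,
                       ne_band = c(12.8, 37.0),
                       prevalence_min_days = 1L) {
  sentinel_energy <- match.arg(sentinel_energy)
  cfg <- list(daypart_starts = as.integer(daypart_starts),
              usual_slots = lapply(usual_slots, as.integer),
              ne1_start = as.integer(ne1_start),
              ne1_criterion = as.numeric(ne1_criterion),
              ne2_width = as.integer(ne2_width),
              ne2_criterion = as.numeric(ne2_criterion),
              ne_strict = isTRUE(ne_strict),
              avg_bedtime = as.integer(avg_bedtime),
              sentinel_energy = sentinel_energy,
              skew_threshold = as.numeric(skew_threshold),
              rare_top_bin_pct = as.numeric(rare_top_bin_pct),
              profile_epsilon = as.numeric(profile_epsilon),
              slot_frac = as.numeric(slot_frac),
              dup_tol = as.numeric(dup_tol),
              ne_percentile = as.numeric(ne_percentile),
              ne_rounding = as.numeric(ne_rounding),
              ne_band = as.numeric(ne_band),
              prevalence_min_days = as.integer(prevalence_min_days))
  names(cfg$daypart_starts) <- names(daypart_starts)
  names(cfg$avg_bedtime) <- names(avg_bedtime)
  validate_config(cfg)
  class(cfg) <- "ler_config"
  cfg
}

validate_config <- function(cfg) {
  req <- c("first_thing", "morning", "afternoon", "evening")
  if (!all(req %in% names(cfg$daypart_starts))) {
    stop("config error in field 'daypart_starts': need names ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(cfg$daypart_starts[req])) {
    stop("config error in field 'daypart_starts': must be increasing",
         call. = FALSE)
  }
  slots <- c("breakfast", "lunch", "dinner")
  if (!all(slots %in% names(cfg$usual_slots))) {
    stop("config error in field 'usual_slots': need names ",
         paste(slots, collapse = ", "), call. = FALSE)
  }
  for (s in slots) {
    v <- cfg$usual_slots[[s]]
    if (length(v) != 2L || v[1] > v[2] || v[1] < 0L || v[2] > 1439L) {
      stop("config error in field 'usual_slots$", s,
           "': need inclusive minute range within 0-1439", call. = FALSE)
    }
  }
  for (f in c("ne1_start", "ne2_width")) {
    if (cfg[[f]] < 0L || cfg[[f]] > 1439L) {
      stop("config error in field '", f, "': outside 0-1439", call. = FALSE)
    }
  }
  for (f in c("ne1_criterion", "ne2_criterion")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 100) {
      stop("config error in field '", f, "': must lie in (0,100)",
           call. = FALSE)
    }
  }
  if (!all(c("weekday", "weekend") %in% names(cfg$avg_bedtime))) {
    stop("config error in field 'avg_bedtime': need weekday and weekend",
         call. = FALSE)
  }
  if (any(cfg$avg_bedtime < 0L | cfg$avg_bedtime > 1439L)) {
    stop("config error in field 'avg_bedtime': outside 0-1439", call. = FALSE)
  }
  if (length(cfg$ne_band) != 2L || cfg$ne_band[1] > cfg$ne_band[2]) {
    stop("config error in field 'ne_band': need lo <= hi", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.ler_config <- function(x, ...) {
  cat("LER study configuration\n")
  cat("  dayparts start:",
      paste(names(x$daypart_starts), format_hhmm(x$daypart_starts),
            sep = "=", collapse = "  "), "\n")
  cat("  usual slots:  ",
      paste(names(x$usual_slots),
            vapply(x$usual_slots,
                   function(v) paste(format_hhmm(v), collapse = "-"), ""),
            sep = "=", collapse = "  "), "\n")
  cat(sprintf("  NE1: >=%s%% TDEI after %s   NE2: >=%s%% TDEI in %d min before bedtime\n",
              x$ne1_criterion, format_hhmm(x$ne1_start), x$ne2_criterion,
              x$ne2_width))
  cat("  average bedtime:",
      paste(names(x$avg_bedtime), format_hhmm(x$avg_bedtime),
            sep = "=", collapse = "  "), "\n")
  cat("  sentinel energy policy:", x$sentinel_energy, "\n")
  invisible(x)
}

#' Read / write a configuration as JSON
#'
#' Configuration files are plain JSON so pipeline runs are reproducible from
#' text alone. Unknown fields are rejected.
#'
#' @param path file path.
#' @return `read_config()` returns a `ler_config`; `write_config()` its
#'   path, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ler_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("config error: unknown field(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("daypart_starts", "avg_bedtime", "ne_band")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$usual_slots)) {
    raw$usual_slots <- lapply(as.list(raw$usual_slots), unlist)
  }
  do.call(ler_config, raw)
}

#' @rdname read_config
#' @param config a `ler_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ler_config"))
  x <- unclass(config)
  ## jsonlite drops names on atomic vectors; named fields go as objects
  for (f in c("daypart_starts", "avg_bedtime")) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
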