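## Clock times are handled as integer minutes since midnight (0..1439).
## Exact integer arithmetic avoids any float drift in window comparisons.

#' Parse clock times to minutes since midnight
#'
#' Accepts `"HH:MM"` and 4-digit `"HHMM"` strings (also 3-digit `"HMM"`,
#' e.g. `"800"`), returning integer minutes since midnight. The historical
#' sentinel codes `"99"` (food found, no recorded time) and `"88"` (database
#' food not matched in the diary) are *not* times and are rejected here;
#' diary readers intercept them before calling this function.
#'
#' @param x character vector of clock times.
#' @return integer vector of minutes since midnight (0-1439). `NA` inputs
#'   stay `NA`; unparseable or out-of-range times raise an error naming the
#'   offending value.
#' @examples
#' parse_hhmm(c("08:15", "0815", "23:59"))
#' @export
parse_hhmm <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  ok_na <- is.na(x) | x == ""
  colon <- grepl("^\\d{1,2}:\\d{2}$", x)
  plain <- grepl("^\\d{3,4}$", x)
  bad <- !(ok_na | colon | plain)
  if (any(bad)) {
    stop("unparseable clock time(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  hh <- integer(length(x)); mm <- integer(length(x))
  if (any(colon)) {
    parts <- strsplit(x[colon], ":", fixed = TRUE)
    hh[colon] <- as.integer(vapply(parts, `[`, "", 1L))
    mm[colon] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  if (any(plain)) {
    v <- as.integer(x[plain])
    hh[plain] <- v %/% 100L
    mm[plain] <- v %% 100L
  }
  keep <- colon | plain
  bad_range <- keep & (hh > 23L | mm > 59L)
  if (any(bad_range)) {
    stop("clock time out of range (00:00-23:59): ",
         paste(unique(x[bad_range]), collapse = ", "), call. = FALSE)
  }
  out[keep] <- hh[keep] * 60L + mm[keep]
  out
}

#' Format minutes since midnight as "HH:MM"
#'
#' @param m integer minutes since midnight; `NA` gives `NA`.
#' @param sep separator, `":"` by default; use `""` for the 4-digit HHMM
#'   form used in the historical meal-slot coding.
#' @return character vector.
#' @examples
#' format_hhmm(495)       # "08:15"
#' format_hhmm(480, "")   # "0800"
#' @export
format_hhmm <- function(m, sep = ":") {
  stopifnot(is.numeric(m))
  out <- rep(NA_character_, length(m))
  ok <- !is.na(m)
  mi <- as.integer(m[ok])
  if (any(mi < 0L | mi > 1439L)) {
    stop("minutes out of range 0-1439", call. = FALSE)
  }
  out[ok] <- sprintf("%02d%s%02d", mi %/% 60L, sep, mi %% 60L)
  out
}

## internal: daypart of a vector of minute times given window start minutes
daypart_of <- function(t, starts) {
  cut(t, breaks = c(-1L, starts[["morning"]] - 1L, starts[["afternoon"]] - 1L,
                    starts[["evening"]] - 1L, 1439L),
      labels = c("first_thing", "morning", "afternoon", "evening"))
}
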