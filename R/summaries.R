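## Cohort description and inference layer: per-variable summaries with a
## skewness-routed display choice, week-vs-weekend paired comparisons,
## Pearson chi-square from printed contingency counts, Spearman
## inter-correlation matrices, and sample-flow arithmetic.

LER_VAR_TYPE <- c(T1a = "categorical", T1b = "categorical",
                  T2 = "continuous", T3 = "continuous",
                  E1a = "continuous", E1b = "continuous",
                  E1c1 = "categorical", E1c2 = "categorical",
                  E2 = "continuous", E3 = "continuous",
                  F1 = "count", F2 = "categorical", F3 = "categorical")

## moment-based sample skewness
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(0)
  m <- mean(x)
  (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
}

#' Summarise LER variables for one stratum
#'
#' Continuous variables with sample skewness above the configured
#' threshold (signed: a pronounced right tail) are displayed as median
#' (IQR), otherwise mean (SD); count
#' variables always as median (IQR); categorical day-count variables as
#' n (%) per category bin, with the top bin merged downward when it holds
#' fewer than `rare_top_bin_pct` percent of children.
#'
#' @param profiles output of [derive_all()].
#' @param stratum stratum to summarise.
#' @param config a [ler_config()].
#' @return an object of class `ler_summary`: a list with one element per
#'   variable, each a list with `type`, `display` (`"mean_sd"`,
#'   `"median_iqr"` or `"categorical"`), the relevant statistics, `n`
#'   (non-missing) and, for categorical variables, a `categories`
#'   data.frame whose percentages use the non-missing denominator.
#' @export
summarise_ler <- function(profiles, stratum = "whole_week",
                          config = ler_config()) {
  stratum <- match.arg(stratum, LER_STRATA)
  p <- as.data.frame(profiles)   # base subsetting: `stratum` is also a column
  p <- p[p$stratum == stratum, ]
  if (nrow(p) == 0L) {
    warning("empty stratum '", stratum, "': nothing to summarise",
            call. = FALSE)
    out <- list()
    class(out) <- "ler_summary"
    attr(out, "stratum") <- stratum
    return(out)
  }
  out <- lapply(LER_VARIABLES, function(v) {
    x <- p[[v]]
    type <- LER_VAR_TYPE[[v]]
    n <- sum(!is.na(x))
    if (type == "categorical") {
      b <- bin_count_variable(x[!is.na(x)], stratum)
      tab <- table(b)
      if (length(tab) > 2L && n > 0 &&
          100 * tab[length(tab)] / n < config$rare_top_bin_pct) {
        lv <- levels(b)
        merged <- paste0(">=", lv[length(lv) - 1L])
        newtab <- c(tab[seq_len(length(tab) - 2L)],
                    sum(tab[length(tab) - 1:0]))
        names(newtab)[length(newtab)] <- merged
        tab <- newtab
      }
      cats <- data.frame(category = names(tab), n = as.integer(tab),
                         pct = if (n > 0) 100 * as.integer(tab) / n else
                           rep(NA_real_, length(tab)))
      list(variable = v, type = type, display = "categorical", n = n,
           categories = cats)
    } else {
      sk <- sample_skewness(x)
      use_median <- type == "count" || sk > config$skew_threshold
      q <- stats::quantile(x, c(.25, .5, .75), na.rm = TRUE, names = FALSE)
      list(variable = v, type = type,
           display = if (use_median) "median_iqr" else "mean_sd",
           n = n, skewness = sk,
           mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
           median = q[2], q1 = q[1], q3 = q[3])
    }
  })
  names(out) <- LER_VARIABLES
  class(out) <- "ler_summary"
  attr(out, "stratum") <- stratum
  out
}

#' @export
print.ler_summary <- function(x, ...) {
  cat("LER summary, stratum:", attr(x, "stratum"), "\n")
  for (v in x) {
    if (v$display == "categorical") {
      cat(sprintf("  %-4s n=%d  %s\n", v$variable, v$n,
                  paste(sprintf("%s: %d (%.1f%%)", v$categories$category,
                                v$categories$n, v$categories$pct),
                        collapse = "  ")))
    } else if (v$display == "median_iqr") {
      cat(sprintf("  %-4s n=%d  median %.2f (IQR %.2f, %.2f)\n",
                  v$variable, v$n, v$median, v$q1, v$q3))
    } else {
      cat(sprintf("  %-4s n=%d  mean %.2f (SD %.2f)\n",
                  v$variable, v$n, v$mean, v$sd))
    }
  }
  invisible(x)
}

#' Compare weekday and weekend strata in paired children
#'
#' Restricted to children present in both the weekdays and weekend strata.
#' Continuous variables use a paired t-test (with the 95% CI of the mean
#' difference, weekday minus weekend); the count variable F1 a Wilcoxon
#' matched-pairs signed-rank test; categorical day-count variables a
#' Pearson chi-square on the 0 vs >=1 day dichotomy (day-count categories
#' differ between the two strata, so the common dichotomy is compared).
#'
#' @param profiles output of [derive_all()].
#' @param config a [ler_config()].
#' @return a `data.table`: `variable`, `test`, `statistic`, `p_value`,
#'   `diff_means`, `ci_lo`, `ci_hi`, `n_pairs`.
#' @export
compare_week_weekend <- function(profiles, config = ler_config()) {
  profiles <- as.data.frame(profiles)
  wd <- profiles[profiles$stratum == "weekdays", ]
  we <- profiles[profiles$stratum == "weekend", ]
  both <- intersect(wd$child_id, we$child_id)
  wd <- wd[match(both, wd$child_id), ]
  we <- we[match(both, we$child_id), ]
  rows <- lapply(LER_VARIABLES, function(v) {
    x <- as.numeric(wd[[v]]); y <- as.numeric(we[[v]])
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    base <- data.table::data.table(variable = v, test = NA_character_,
                                   statistic = NA_real_, p_value = NA_real_,
                                   diff_means = NA_real_, ci_lo = NA_real_,
                                   ci_hi = NA_real_, n_pairs = n)
    if (n < 2L) {
      base$test <- "undefined"
      return(base)
    }
    type <- LER_VAR_TYPE[[v]]
    if (type == "continuous") {
      if (stats::sd(x - y) == 0) {
        ## degenerate paired t: all differences equal
        d <- mean(x - y)
        base$test <- "paired_t"
        base$statistic <- if (d == 0) 0 else Inf
        base$p_value <- if (d == 0) 1 else 0
        base$diff_means <- d; base$ci_lo <- d; base$ci_hi <- d
        return(base)
      }
      tt <- stats::t.test(x, y, paired = TRUE)
      base$test <- "paired_t"
      base$statistic <- unname(tt$statistic)
      base$p_value <- tt$p.value
      base$diff_means <- unname(tt$estimate)
      base$ci_lo <- tt$conf.int[1]; base$ci_hi <- tt$conf.int[2]
    } else if (type == "count") {
      if (all(x == y)) {
        base$test <- "wilcoxon_signed_rank"
        base$statistic <- 0; base$p_value <- 1
        return(base)
      }
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                exact = FALSE,
                                                correct = FALSE))
      base$test <- "wilcoxon_signed_rank"
      base$statistic <- unname(wt$statistic)
      base$p_value <- wt$p.value
    } else {
      tab <- rbind(weekdays = c(sum(x == 0), sum(x >= 1)),
                   weekend = c(sum(y == 0), sum(y >= 1)))
      base$test <- "chi_square"
      if (any(colSums(tab) == 0)) return(base)
      cs <- chi_square_from_table(tab)
      base$statistic <- cs$statistic
      base$p_value <- cs$p_value
    }
    base
  })
  data.table::rbindlist(rows)
}

#' Pearson chi-square statistic from a contingency table
#'
#' Plain Pearson statistic without continuity correction:
#' `sum((O - E)^2 / E)` with `E` the product-marginal expectation,
#' `df = (r-1)(c-1)`.
#'
#' @param counts r x c matrix of non-negative counts; every row and column
#'   sum must be positive.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' chi_square_from_table(rbind(c(1177, 1079), c(1586, 1578)))
#' @export
chi_square_from_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(is.na(counts))) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  n <- sum(counts)
  expected <- outer(rs, cs) / n
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Spearman inter-correlation matrix of the 13 LER variables
#'
#' Rank correlation with average ranks for ties, pairwise-complete
#' observations, with the pairwise n recorded per cell. Cells involving a
#' constant variable are undefined (`NA`) and listed in the `undefined`
#' attribute rather than silently zeroed.
#'
#' @param profiles output of [derive_all()].
#' @param stratum stratum whose profiles enter the matrix.
#' @return an object of class `ler_cor`: list with `rho` (13 x 13),
#'   `n` (pairwise counts) and `undefined` (variable names with zero
#'   variance).
#' @export
spearman_matrix <- function(profiles, stratum = "whole_week") {
  stratum <- match.arg(stratum, LER_STRATA)
  p <- as.data.frame(profiles)   # base subsetting: `stratum` is also a column
  p <- p[p$stratum == stratum, ]
  m <- as.matrix(p[, LER_VARIABLES])
  storage.mode(m) <- "double"
  if (sum(stats::complete.cases(m)) < 3L) {
    stop("need at least 3 children with complete pairwise values",
         call. = FALSE)
  }
  rho <- suppressWarnings(stats::cor(m, method = "spearman",
                                     use = "pairwise.complete.obs"))
  nonmiss <- !is.na(m)
  nmat <- crossprod(nonmiss)
  const <- LER_VARIABLES[apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || all(v == v[1])
  })]
  diag(rho) <- ifelse(LER_VARIABLES %in% const, NA_real_, 1)
  out <- list(rho = rho, n = nmat, undefined = const, stratum = stratum)
  class(out) <- "ler_cor"
  out
}

#' @export
print.ler_cor <- function(x, ...) {
  cat("Spearman inter-correlations,", x$stratum, "stratum\n")
  print(round(x$rho, 2))
  if (length(x$undefined)) {
    cat("undefined (constant):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample-flow accounting
#'
#' Counts children at each stage of the analysis flow, either from a
#' record table (eligibility computed from recorded days) or from supplied
#' stage counts, and derives the dependent quantities: response rate,
#' whole-week n (timed minus incomplete), and the week-and-weekend overlap
#' (whole-week minus all-weekday children).
#'
#' @param records optional record table; when given, `timed`,
#'   `n_incomplete`, `n_all_weekday` and the per-stratum eligible counts
#'   are computed from it.
#' @param invited,completed optional upstream counts (children invited /
#'   with completed diaries) for the response rate.
#' @param timed,n_incomplete,n_all_weekday stage counts, used when
#'   `records` is `NULL`.
#' @return an object of class `ler_flow`: named list of counts and
#'   percentages (`response_rate_pct`, `n_whole_week`,
#'   `n_week_weekend_overlap`, ...).
#' @export
flow_counts <- function(records = NULL, invited = NULL, completed = NULL,
                        timed = NULL, n_incomplete = NULL,
                        n_all_weekday = NULL) {
  n_weekdays_elig <- n_weekend_elig <- NULL
  if (!is.null(records)) {
    rec <- data.table::as.data.table(records)
    if (nrow(rec) == 0L) {
      timed <- 0L; n_incomplete <- 0L; n_all_weekday <- 0L
      n_weekdays_elig <- 0L; n_weekend_elig <- 0L
    } else {
      dd <- unique(rec[, .(child_id, day_index, day_type)])
      per <- dd[, .(n_days = .N,
                    n_wd = sum(day_type == "weekday"),
                    n_we = sum(day_type == "weekend")), by = child_id]
      timed <- nrow(per)
      n_incomplete <- sum(per$n_days < 3L)
      n_all_weekday <- sum(per$n_days == 3L & per$n_wd == 3L)
      n_weekdays_elig <- sum(per$n_wd >= 2L)
      n_weekend_elig <- sum(per$n_we >= 1L)
    }
  }
  out <- list(invited = invited, completed = completed, timed = timed,
              n_incomplete = n_incomplete,
              n_weekdays_eligible = n_weekdays_elig,
              n_weekend_eligible = n_weekend_elig)
  out$response_rate_pct <-
    if (!is.null(invited) && !is.null(completed) && invited > 0) {
      100 * completed / invited
    } else NULL
  out$n_whole_week <-
    if (!is.null(timed) && !is.null(n_incomplete)) timed - n_incomplete
    else NULL
  out$n_week_weekend_overlap <-
    if (!is.null(out$n_whole_week) && !is.null(n_all_weekday)) {
      out$n_whole_week - n_all_weekday
    } else NULL
  class(out) <- "ler_flow"
  out
}

#' @export
print.ler_flow <- function(x, ...) {
  show <- function(nm, v, fmt = "%d") {
    if (!is.null(v)) cat(sprintf(paste0("  %-24s ", fmt, "\n"), nm, v))
  }
  cat("Sample flow\n")
  show("invited", x$invited); show("completed diaries", x$completed)
  show("response rate (%)", x$response_rate_pct, "%.1f")
  show("timed subsample", x$timed)
  show("< 3 days recorded", x$n_incomplete)
  show("whole-week eligible", x$n_whole_week)
  show("weekday eligible", x$n_weekdays_eligible)
  show("weekend eligible", x$n_weekend_eligible)
  show("week & weekend overlap", x$n_week_weekend_overlap)
  invisible(x)
}
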