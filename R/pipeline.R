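## End-to-end orchestration: simulate -> validate -> derive -> calibrate ->
## summarise, driven by a JSON run configuration, with a manifest recording
## config snapshot, input digests, seed, stage timings and outputs.

#' Run the LER pipeline
#'
#' The run configuration is a JSON file (or equivalent list) with fields:
#' `seed` (integer), `out_dir`, either `simulate` (a list of
#' [gen_params()] overrides) or `diary` + `bedtimes` (paths), optional
#' `study` ([ler_config()] overrides), and optional `stages` (default all
#' of validate, derive, calibrate, summarise, plus simulate when
#' configured). Stages run in order and abort with a stage-named error.
#'
#' @param config path to a JSON run config, or a list.
#' @param out_dir output directory override.
#' @return the run manifest (class `ler_manifest`), invisibly written to
#'   `manifest.json` in `out_dir`: config snapshot, seed, input file
#'   digests, stage timings, outputs with digests, warnings, and one
#'   exclusion line per child dropped from every stratum.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config error: file not found: ", config, call. = FALSE)
    }
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config error in field 'out_dir': required",
                             call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  study <- do.call(ler_config, if (is.null(cfg$study)) list()
                               else relist_config(cfg$study))
  stages <- cfg$stages
  if (is.null(stages)) {
    stages <- c(if (!is.null(cfg$simulate)) "simulate",
                "validate", "derive", "calibrate", "summarise")
  }
  manifest <- list(config = cfg, seed = seed, stages = list(),
                   inputs = list(), outputs = character(),
                   warnings = character(), exclusions = character())
  warns <- character()
  note <- function(...) warns <<- c(warns, sprintf(...))
  timing <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }
  outfile <- function(name) {
    path <- file.path(out_dir, name)
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }

  records <- NULL; bedtimes <- NULL; cohort <- NULL
  if ("simulate" %in% stages) {
    gp_args <- if (is.null(cfg$simulate)) list() else as.list(cfg$simulate)
    if (is.null(gp_args$seed)) gp_args$seed <- seed
    cohort <- timing("simulate", {
      coh <- generate_cohort(do.call(gen_params, gp_args))
      write_diary(coh$records, outfile("diary.csv"))
      write_bedtimes(coh$bedtimes, outfile("bedtimes.csv"))
      write.csv(coh$truth$children, outfile("truth_children.csv"),
                row.names = FALSE)
      write.csv(coh$truth$days, outfile("truth_days.csv"),
                row.names = FALSE)
      jsonlite::write_json(unclass(coh$params), outfile("gen_params.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      coh
    })
    records <- cohort$records; bedtimes <- cohort$bedtimes
  } else {
    if (is.null(cfg$diary) || is.null(cfg$bedtimes)) {
      stop("config error in field 'diary'/'bedtimes': required when the ",
           "simulate stage is disabled", call. = FALSE)
    }
    records <- read_diary(cfg$diary)
    bedtimes <- read_bedtimes(cfg$bedtimes)
    manifest$inputs <- list(diary = unname(tools::md5sum(cfg$diary)),
                            bedtimes = unname(tools::md5sum(cfg$bedtimes)))
  }

  if ("validate" %in% stages) {
    rep <- timing("validate", validate_cohort(records, bedtimes))
    if (nrow(rep$violations) > 0) {
      note("validation: %d violation(s)", nrow(rep$violations))
    }
    jsonlite::write_json(
      list(n_records = rep$n_records, n_no_time = rep$n_no_time,
           n_unmatched = rep$n_unmatched, n_children = rep$n_children,
           bedtime_coverage = rep$bedtime_coverage,
           n_violations = nrow(rep$violations)),
      outfile("validation.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }

  profiles <- NULL
  if ("derive" %in% stages) {
    profiles <- timing("derive", derive_all(records, bedtimes, study))
    for (ch in attr(profiles, "excluded")) {
      manifest$exclusions <- c(manifest$exclusions,
        sprintf("child %s: no eligible stratum (fewer than the required recorded days)", ch))
    }
    write.csv(as.data.frame(profiles), outfile("ler_profiles.csv"),
              row.names = FALSE, na = "")
  }

  if ("calibrate" %in% stages) {
    cal <- timing("calibrate", {
      prof <- compute_ei_profile(records, bedtimes)
      bounds <- tryCatch(
        infer_window_boundaries(prof, study$profile_epsilon,
                                study$slot_frac),
        error = function(e) {
          note("calibrate: %s", conditionMessage(e))
          NULL
        })
      cand <- compare_candidate_windows(records,
                                        bedtimes = bedtimes,
                                        config = study)
      thr <- calibrate_ne_threshold(records,
                                    window = list(type = "after",
                                                  start = study$ne1_start),
                                    bedtimes = bedtimes, config = study)
      list(profile = prof, boundaries = bounds, candidates = cand,
           threshold = thr)
    })
    jsonlite::write_json(
      list(profile_bins = cal$profile$bins,
           n_child_days = cal$profile$n_child_days,
           boundaries = as.list(cal$boundaries$boundaries),
           usual_slots = cal$boundaries$usual_slots,
           candidates = cal$candidates,
           threshold = cal$threshold[c("percentile",
                                       "raw_percentile_value",
                                       "criterion", "prevalence",
                                       "band", "accepted",
                                       "n_children")]),
      outfile("calibration.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }

  if ("summarise" %in% stages) {
    if (is.null(profiles)) {
      stop("stage 'summarise' failed: derive stage did not run",
           call. = FALSE)
    }
    timing("summarise", {
      for (s in LER_STRATA) {
        if (!any(profiles$stratum == s)) next
        write.csv(summary_as_table(summarise_ler(profiles, s, study)),
                  outfile(paste0("summary_", s, ".csv")),
                  row.names = FALSE, na = "")
        cm <- spearman_matrix(profiles, s)
        write.csv(data.frame(variable = rownames(cm$rho),
                             round(cm$rho, 6), check.names = FALSE),
                  outfile(paste0("correlation_", s, ".csv")),
                  row.names = FALSE, na = "")
      }
      write.csv(as.data.frame(compare_week_weekend(profiles, study)),
                outfile("comparison_week_weekend.csv"),
                row.names = FALSE, na = "")
    })
  }

  manifest$warnings <- warns
  manifest$output_digests <- as.list(tools::md5sum(manifest$outputs))
  class(manifest) <- "ler_manifest"
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), mpath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

## run-config "study" block arrives from JSON with lists; coerce to the
## shapes ler_config() expects
relist_config <- function(study) {
  study <- as.list(study)
  for (f in c("daypart_starts", "avg_bedtime", "ne_band")) {
    if (!is.null(study[[f]])) study[[f]] <- unlist(study[[f]])
  }
  if (!is.null(study$usual_slots)) {
    study$usual_slots <- lapply(as.list(study$usual_slots), unlist)
  }
  study
}

#' Flatten a summary object into a long table
#'
#' @param s a `ler_summary`.
#' @return data.frame with one row per variable (continuous/count) or per
#'   category (categorical).
#' @export
summary_as_table <- function(s) {
  rows <- lapply(s, function(v) {
    if (v$display == "categorical") {
      data.frame(variable = v$variable, type = v$type,
                 display = v$display, n = v$n,
                 category = v$categories$category,
                 cat_n = v$categories$n, cat_pct = v$categories$pct,
                 mean = NA_real_, sd = NA_real_, median = NA_real_,
                 q1 = NA_real_, q3 = NA_real_, skewness = NA_real_)
    } else {
      data.frame(variable = v$variable, type = v$type,
                 display = v$display, n = v$n,
                 category = NA_character_, cat_n = NA_integer_,
                 cat_pct = NA_real_, mean = v$mean, sd = v$sd,
                 median = v$median, q1 = v$q1, q3 = v$q3,
                 skewness = v$skewness)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.ler_manifest <- function(x, ...) {
  cat("LER pipeline manifest (seed", x$seed, ")\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-10s %6.2fs\n", s, x$stages[[s]]))
  }
  cat("  outputs:", length(x$outputs), "files\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  if (length(x$exclusions)) cat("  excluded children:",
                                length(x$exclusions), "\n")
  invisible(x)
}
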