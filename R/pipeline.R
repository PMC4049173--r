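# End-to-end pipeline: simulate -> metrics -> peri-CS typing -> group stats,
# driven by one seeded, serializable configuration.

#' Pipeline run configuration
#'
#' Bundles everything a reproducible run needs: the master seed, the cohort
#' specification, the analysis options, and an optional output directory.
#' Re-running the same configuration reproduces every output.
#'
#' @param seed Integer master seed; all stage randomness derives from it.
#' @param cohort List of entries `list(preset = <cell_preset>, n_cells = n)`;
#'   defaults to the published cohort sizes (47 zebrin-negative, 57
#'   zebrin-positive cells).
#' @param duration Recording duration per cell (s).
#' @param bin_width_ms Peri-CS histogram bin width (ms).
#' @param classifier Named list of overrides passed to
#'   [classify_response_type()].
#' @param out_dir Optional output directory; when given, the run writes the
#'   spike files, manifest, metrics table, peri-CS table, group statistics
#'   (JSON) and a text report there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       cohort = list(
                         list(preset = zebrin_preset("negative"), n_cells = 47),
                         list(preset = zebrin_preset("positive"), n_cells = 57)),
                       duration = 120,
                       bin_width_ms = 5,
                       classifier = list(),
                       out_dir = NULL) {
  cfg <- structure(list(seed = as.integer(seed), cohort = cohort,
                        duration = duration, bin_width_ms = bin_width_ms,
                        classifier = classifier, out_dir = out_dir),
                   class = "run_config")
  # validate eagerly so misconfiguration aborts before any stage runs
  population_config(cohort, duration = duration, seed = seed)
  check_number(bin_width_ms, "bin_width_ms", lower = 0, strict_lower = TRUE)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]: top-level `seed`, `duration`,
#' `bin_width_ms`, `out_dir`, and a `cohort` list whose entries give
#' `n_cells` plus either `zebrin: negative/positive` (preset defaults) or
#' explicit preset fields overriding them.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- lapply(y$cohort, function(e) {
    base <- if (!is.null(e$zebrin) && e$zebrin %in% c("negative", "positive")) {
      zebrin_preset(e$zebrin)
    } else {
      NULL
    }
    fields <- e[setdiff(names(e), c("zebrin", "n_cells"))]
    preset <- if (is.null(base)) {
      do.call(cell_preset, fields)
    } else if (length(fields)) {
      do.call(cell_preset, utils::modifyList(
        unclass(base)[c("zebrin_identity", "ss_rate_mean", "ss_rate_sd",
                        "ss_shape", "cs_rate", "cs_rate_sd", "cf_pause_ms",
                        "amplitude_drift")], fields))
    } else {
      base
    }
    list(preset = preset, n_cells = e$n_cells)
  })
  run_config(seed = y$seed %||% 1, cohort = cohort,
             duration = y$duration %||% 120,
             bin_width_ms = y$bin_width_ms %||% 5,
             classifier = y$classifier %||% list(),
             out_dir = y$out_dir)
}

pipeline_log <- function(con, ...) {
  msg <- sprintf(...)
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> per-cell metrics -> peri-CS response typing ->
#' group statistics as one deterministic run. Group statistics comprise the
#' pooled t comparisons of SS rate, CS rate and mean CV2 between
#' zebrin-negative and zebrin-positive cells, and the Pearson chi-squared
#' test on the facilitation-by-zebrin contingency table. Any stage failure
#' aborts with the stage name and the offending cell ids.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return A list with `manifest`, `metrics`, `pericss`, `stats` and
#'   `report` (character vector of report lines), invisibly when writing to
#'   disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    stop_invalid_config("`config` must be a run_config or a YAML path")
  }
  out_dir <- config$out_dir
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(log_con), add = TRUE)
  }
  pipeline_log(log_con, "pipeline start | seed %d | %s cells x %g s | zebratrain %s",
               config$seed,
               paste(vapply(config$cohort, function(e) e$n_cells, numeric(1)),
                     collapse = "+"),
               config$duration,
               as.character(utils::packageVersion("zebratrain")))

  run_stage <- function(stage, ids, fn) {
    failures <- character()
    out <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      out[[i]] <- tryCatch(fn(i), error = function(e) {
        failures[[length(failures) + 1L]] <<- ids[i]
        conditionMessage(e)
      })
    }
    if (length(failures)) {
      zt_stop("zt_runtime_error", sprintf(
        "stage '%s' failed for cells: %s", stage,
        paste(failures, collapse = ", ")))
    }
    out
  }

  pipeline_log(log_con, "stage simulate")
  pop <- generate_population(population_config(
    config$cohort, duration = config$duration, seed = config$seed))
  if (!is.null(out_dir)) write_population(pop, file.path(out_dir, "spikes"))

  pipeline_log(log_con, "stage metrics (%d cells)", length(pop$recordings))
  ids <- vapply(pop$recordings, function(r) r$cell_id, character(1))
  metrics <- do.call(rbind, run_stage("metrics", ids, function(i) {
    cell_metrics(pop$recordings[[i]])
  }))

  pipeline_log(log_con, "stage pericss")
  pericss_rows <- run_stage("pericss", ids, function(i) {
    rec <- pop$recordings[[i]]
    prof <- peri_cs_histogram(rec$ss_times, rec$cs_times, rec$duration,
                              bin_width_ms = config$bin_width_ms)
    prof <- suppressWarnings(do.call(
      classify_response_type, c(list(prof), config$classifier)))
    data.frame(cell_id = rec$cell_id,
               zebrin_identity = rec$zebrin_identity,
               n_cs = prof$n_cs,
               baseline_hz = prof$baseline_hz,
               pause_end_ms = prof$diagnostics$pause_end_ms,
               osc_t = prof$diagnostics$osc_t,
               type = prof$type,
               true_type = rec$ground_truth$type %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  pericss <- do.call(rbind, pericss_rows)

  pipeline_log(log_con, "stage stats")
  stats_out <- list()
  by_id <- split(metrics, metrics$zebrin_identity)
  if (all(c("negative", "positive") %in% names(by_id))) {
    stats_out$ss_rate_t <- two_sample_t(by_id$negative$ss_rate,
                                        by_id$positive$ss_rate)
    stats_out$cs_rate_t <- two_sample_t(by_id$negative$cs_rate,
                                        by_id$positive$cs_rate)
    cv2_ok_n <- by_id$negative$ss_mean_cv2[!is.na(by_id$negative$ss_mean_cv2)]
    cv2_ok_p <- by_id$positive$ss_mean_cv2[!is.na(by_id$positive$ss_mean_cv2)]
    if (length(cv2_ok_n) >= 2 && length(cv2_ok_p) >= 2) {
      stats_out$cv2_t <- two_sample_t(cv2_ok_n, cv2_ok_p)
    }
    tab <- type_contingency(pericss$type, pericss$zebrin_identity)
    stats_out$facilitation_table <- tab
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      stats_out$facilitation_chi2 <- pearson_chi2(tab)
    }
  }

  report <- c(
    sprintf("zebratrain pipeline report (seed %d)", config$seed),
    sprintf("cells: %d | duration: %g s", nrow(metrics), config$duration),
    "",
    "group means (SS rate, Hz):",
    vapply(names(by_id), function(g) {
      sprintf("  zebrin %s: n = %d, %.1f +/- %.1f Hz", g, nrow(by_id[[g]]),
              mean(by_id[[g]]$ss_rate), sd(by_id[[g]]$ss_rate))
    }, character(1)),
    "",
    "response types:",
    vapply(names(by_id), function(g) {
      cnt <- table(factor(pericss$type[pericss$zebrin_identity == g],
                          levels = RESPONSE_TYPES))
      sprintf("  zebrin %s: %s", g,
              paste(sprintf("%s %d", names(cnt), cnt), collapse = ", "))
    }, character(1)))
  if (!is.null(stats_out$ss_rate_t)) {
    report <- c(report, "", sprintf(
      "SS rate negative vs positive: t = %.3f, df = %d, p = %.3g",
      stats_out$ss_rate_t$value, stats_out$ss_rate_t$df, stats_out$ss_rate_t$p))
  }
  if (!is.null(stats_out$cs_rate_t)) {
    report <- c(report, sprintf(
      "CS rate negative vs positive: t = %.3f, df = %d, p = %.3g",
      stats_out$cs_rate_t$value, stats_out$cs_rate_t$df, stats_out$cs_rate_t$p))
  }
  if (!is.null(stats_out$facilitation_chi2)) {
    report <- c(report, sprintf(
      "facilitation type by zebrin: chi2 = %.3f, p = %.3g",
      stats_out$facilitation_chi2$value, stats_out$facilitation_chi2$p))
  }

  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(pericss, file.path(out_dir, "pericss.csv"), row.names = FALSE)
    stats_json <- lapply(stats_out, function(s) {
      if (inherits(s, "group_comparison")) {
        list(statistic = s$statistic, value = s$value, df = s$df, p = s$p)
      } else if (is.matrix(s)) {
        as.data.frame(s)
      } else {
        s
      }
    })
    jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report, file.path(out_dir, "report.txt"))
    pipeline_log(log_con, "outputs written to %s", out_dir)
  }
  pipeline_log(log_con, "pipeline done")
  res <- list(manifest = pop$manifest, metrics = metrics, pericss = pericss,
              stats = stats_out, report = report)
  if (is.null(out_dir)) res else invisible(res)
}
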