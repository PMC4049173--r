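# Reading and writing spike-time tables, manifests and intensity tables.
# Time unit on disk is seconds with 6 decimals (microsecond resolution).

#' Write a recording to a delimited spike-time file
#'
#' One row per event with columns `cell_id`, `event_type` (`SS`/`CS`) and
#' `time_s` (seconds, 6 decimals), sorted by time.
#'
#' @param recording A [spike_train_recording()].
#' @param file Output path (CSV).
#' @return The path, invisibly.
#' @export
write_recording <- function(recording, file) {
  stopifnot(inherits(recording, "spike_train_recording"))
  df <- rbind(
    data.frame(cell_id = recording$cell_id, event_type = "SS",
               time_s = recording$ss_times, stringsAsFactors = FALSE),
    data.frame(cell_id = recording$cell_id, event_type = "CS",
               time_s = recording$cs_times, stringsAsFactors = FALSE))
  df <- df[order(df$time_s), , drop = FALSE]
  df$time_s <- sprintf("%.6f", df$time_s)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a recording from a spike-time file
#'
#' Parses a delimited spike-time table (columns `cell_id`, `event_type`,
#' `time_s`) and assembles a validated recording using the metadata of a
#' manifest entry. Validation failures (unknown event type, negative,
#' out-of-range or non-increasing times) name the file and the offending
#' row.
#'
#' @param file Path to the spike-time CSV.
#' @param manifest_entry A list (or one-row data frame) with at least
#'   `duration`, and optionally `cell_id`, `zebrin_identity`, `lobule`,
#'   `context`, `ground_truth`.
#' @return A [spike_train_recording()].
#' @export
read_recording <- function(file, manifest_entry) {
  if (!file.exists(file)) {
    stop_validation(sprintf("spike file '%s' does not exist", file))
  }
  entry <- as.list(manifest_entry)
  if (is.null(entry$duration)) {
    stop_validation("manifest entry must provide `duration`")
  }
  df <- read.csv(file, stringsAsFactors = FALSE,
                 colClasses = c(cell_id = "character",
                                event_type = "character",
                                time_s = "numeric"))
  if (!all(c("cell_id", "event_type", "time_s") %in% names(df))) {
    stop_validation(sprintf(
      "'%s' must have columns cell_id, event_type, time_s", file))
  }
  bad <- which(!df$event_type %in% c("SS", "CS"))
  if (length(bad)) {
    stop_validation(sprintf(
      "'%s' row %d: unknown event_type '%s' (expected SS or CS)",
      file, bad[1L], df$event_type[bad[1L]]))
  }
  bad <- which(!is.finite(df$time_s) | df$time_s < 0 |
                 df$time_s > entry$duration)
  if (length(bad)) {
    stop_validation(sprintf(
      "'%s' row %d: time %s s outside [0, %g]",
      file, bad[1L], format(df$time_s[bad[1L]]), entry$duration))
  }
  for (ev in c("SS", "CS")) {
    rows <- which(df$event_type == ev)
    if (length(rows) > 1L) {
      nd <- which(diff(df$time_s[rows]) <= 0)
      if (length(nd)) {
        stop_validation(sprintf(
          "'%s' row %d: %s times not strictly increasing",
          file, rows[nd[1L] + 1L], ev))
      }
    }
  }
  gt <- entry$ground_truth
  spike_train_recording(
    cell_id = entry$cell_id %||% df$cell_id[1L] %||% "cell",
    zebrin_identity = entry$zebrin_identity %||% "unknown",
    lobule = entry$lobule %||% NA_character_,
    context = entry$context %||% "in_vivo",
    duration = entry$duration,
    ss_times = df$time_s[df$event_type == "SS"],
    cs_times = df$time_s[df$event_type == "CS"],
    ground_truth = if (is.list(gt)) gt else NULL)
}

#' Write a cohort to a directory
#'
#' Writes one spike-time CSV per cell plus a JSON manifest recording every
#' cell's metadata, ground truth and file name.
#'
#' @param population The list returned by [generate_population()], or any
#'   list of recordings.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_population <- function(population, dir) {
  recs <- if (!is.null(population$recordings)) population$recordings else population
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(recs, function(rec) {
    fname <- paste0(rec$cell_id, ".csv")
    write_recording(rec, file.path(dir, fname))
    list(cell_id = rec$cell_id, file = fname,
         zebrin_identity = rec$zebrin_identity,
         lobule = rec$lobule, context = rec$context,
         duration = rec$duration,
         ground_truth = rec$ground_truth)
  })
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest_path)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_population()].
#' @return A list with `recordings` and the parsed `manifest` entries.
#' @export
read_population <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_validation(sprintf("manifest '%s' does not exist", manifest_path))
  }
  entries <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  recs <- lapply(entries, function(e) {
    read_recording(file.path(dir, e$file), e)
  })
  list(recordings = recs, manifest = entries)
}

#' Normalize zebrin staining intensities by background
#'
#' Computes the per-row soma / background (granule cell layer) intensity
#' ratio and averages the ratios per lobule across sections. The staining
#' convention is preserved as-is: high normalized values mean weak zebrin
#' staining.
#'
#' @param table Data frame with columns `lobule`, `soma` and `background`
#'   (one row per section), intensities > 0.
#' @return A data frame with columns `lobule` and `intensity` (mean
#'   soma/background ratio).
#' @export
normalize_intensity <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("lobule", "soma", "background") %in% names(table))) {
    stop_validation("intensity table must have columns lobule, soma, background")
  }
  bad <- which(!is.finite(table$background) | table$background <= 0)
  if (length(bad)) {
    stop_validation(sprintf(
      "intensity table row %d: background intensity must be > 0", bad[1L]))
  }
  bad <- which(!is.finite(table$soma) | table$soma <= 0)
  if (length(bad)) {
    stop_validation(sprintf(
      "intensity table row %d: soma intensity must be > 0", bad[1L]))
  }
  ratio <- table$soma / table$background
  out <- aggregate(ratio, by = list(lobule = table$lobule), FUN = mean)
  names(out)[2L] <- "intensity"
  out[order(match(out$lobule, unique(table$lobule))), , drop = FALSE]
}
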