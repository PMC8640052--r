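#' Read and write the pipeline's delimited-text tables
#'
#' All interchange files are tab-separated text with a header row. Each
#' schema is validated on read; violations raise an error naming the file
#' and the offending column.
#'
#' @name crossgaze-io
NULL

schema_defs <- function() list(
  trials = list(
    required = c("participant_id", "task", "block", "trial_index",
                 "comparison_speed", "comparison_tta", "standard_first",
                 "approach_side"),
    numeric = c("block", "trial_index", "comparison_speed",
                "comparison_tta"),
    logical = "standard_first"),
  gaze = list(
    required = c("trial_id", "interval", "t_ms", "gaze_x_deg",
                 "gaze_y_deg", "pupil_valid"),
    numeric = c("t_ms", "gaze_x_deg", "gaze_y_deg"),
    logical = "pupil_valid"),
  events = list(
    required = c("trial_id", "kind", "onset_ms", "offset_ms"),
    numeric = c("onset_ms", "offset_ms"),
    logical = character(0)),
  metrics = list(
    required = c("trial_id", "interval", "participant_id", "task",
                 "window", gaze_feature_names()),
    numeric = gaze_feature_names(),
    logical = character(0))
)

check_schema <- function(df, schema, path) {
  def <- schema_defs()[[schema]]
  missing <- setdiff(def$required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  for (col in def$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad))
      stop(sprintf("%s: column '%s' not numeric at row %d", path, col,
                   bad[1]))
    df[[col]] <- v
  }
  for (col in def$logical) df[[col]] <- as.logical(df[[col]])
  df
}

#' Write a table in the package's TSV dialect
#' @param df data frame.
#' @param path output file.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table and validate it against a named schema
#' @param path input file.
#' @param schema one of `"trials"`, `"gaze"`, `"events"`, `"metrics"`.
#' @return A tibble.
#' @export
read_tsv_table <- function(path, schema = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!is.null(schema)) df <- check_schema(df, schema, path)
  tibble::as_tibble(df)
}

#' Serialize a dataset's gaze traces to one file per participant-session
#'
#' Columns: trial_id, interval, t_ms, gaze_x_deg, gaze_y_deg, pupil_valid.
#'
#' @param dataset a `crossgaze_dataset`.
#' @param dir output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_gaze_traces <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- vapply(dataset$traces, function(tr)
    paste(tr$participant_id, tr$task, sep = "_"), "")
  paths <- character(0)
  for (k in unique(key)) {
    rows <- lapply(dataset$traces[key == k], function(tr) {
      data.frame(trial_id = tr$trial_id, interval = tr$interval,
                 t_ms = tr$samples$t_ms,
                 gaze_x_deg = tr$samples$gaze_x,
                 gaze_y_deg = tr$samples$gaze_y,
                 pupil_valid = tr$samples$pupil_valid)
    })
    p <- file.path(dir, paste0("gaze_", k, ".tsv"))
    write_tsv_table(do.call(rbind, rows), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read gaze traces written by [write_gaze_traces()]
#'
#' @param paths TSV files.
#' @param fs sampling rate (Hz) recorded into each trace.
#' @return Named list of `gaze_trace` objects (no ground truth).
#' @export
read_gaze_traces <- function(paths, fs = NULL) {
  out <- list()
  for (p in paths) {
    df <- read_tsv_table(p, schema = "gaze")
    for (k in unique(paste(df$trial_id, df$interval))) {
      sel <- paste(df$trial_id, df$interval) == k
      d <- df[sel, ]
      rate <- fs %||% (1000 / diff(d$t_ms[1:2]))
      out[[paste(d$trial_id[1], d$interval[1], sep = "_")]] <-
        structure(list(trial_id = d$trial_id[1], interval = d$interval[1],
                       participant_id = NA_character_, task = NA_character_,
                       fs = rate,
                       samples = tibble::tibble(
                         t_ms = d$t_ms, gaze_x = d$gaze_x_deg,
                         gaze_y = d$gaze_y_deg,
                         pupil_valid = d$pupil_valid),
                       target = NULL, truth = NULL),
                  class = "gaze_trace")
    }
  }
  out
}

#' Serialize event labels
#' @param events named list of `event_labels` keyed by trial id.
#' @param path output TSV.
#' @export
write_event_labels <- function(events, path) {
  rows <- lapply(names(events), function(id) {
    ev <- events[[id]]
    rbind(
      if (nrow(ev$saccades))
        data.frame(trial_id = id, kind = "saccade",
                   onset_ms = ev$saccades$onset_ms,
                   offset_ms = ev$saccades$offset_ms,
                   amplitude_deg = ev$saccades$amplitude),
      if (nrow(ev$blinks))
        data.frame(trial_id = id, kind = "blink",
                   onset_ms = ev$blinks$onset_ms,
                   offset_ms = ev$blinks$offset_ms,
                   amplitude_deg = NA_real_))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = character(0), kind = character(0),
               onset_ms = numeric(0), offset_ms = numeric(0),
               amplitude_deg = numeric(0))
  write_tsv_table(df, path)
}
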