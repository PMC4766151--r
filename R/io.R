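#' Read a movement-record CSV into an event table
#'
#' Expects a header row with columns `date` (ISO-8601 date or integer day
#' index; auto-detected), `source` and `target`; any extra columns (batch
#' size, animal type, ...) are ignored. Calendar dates are mapped to 1-based
#' day indices relative to `origin` (default: the earliest date in the
#' file). Malformed rows are collected and reported with their line numbers;
#' any malformed row aborts the run. Self-contacts (`source == target`) are
#' dropped with a warning by default.
#'
#' @param path Path to the CSV file.
#' @param origin Optional origin date (`Date` or `"YYYY-MM-DD"`); day 1 is
#'   `origin` itself. Ignored for integer-day input.
#' @param strict If `TRUE`, self-contacts are an error instead of a warning.
#' @param quiet Suppress the summary message.
#' @return A tibble of events (`day`, `from`, `to`) sorted by day, with
#'   attributes `nodes` (the union of endpoints) and `period_length`
#'   (largest day index).
#' @export
read_events <- function(path, origin = NULL, strict = FALSE, quiet = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("date", "source", "target")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "temponet_error_parameter")
  }
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  problems <- character()
  int_like <- grepl("^\\s*\\d+\\s*$", raw$date)
  if (all(int_like)) {
    day <- as.integer(raw$date)
    if (!quiet) inform("Interpreting `date` as integer day indices.")
  } else {
    dates <- as.Date(raw$date, format = "%Y-%m-%d")
    bad <- which(is.na(dates))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("line %d: unparseable date '%s'",
                                      line[bad], raw$date[bad]))
      dates[bad] <- as.Date("1970-01-01")
    }
    good <- setdiff(seq_along(dates), bad)
    if (is.null(origin)) {
      if (length(good) == 0) {
        abort("No parseable dates to infer an origin from.",
              class = "temponet_error_validation")
      }
      origin <- min(dates[good])
    }
    origin <- as.Date(origin)
    day <- as.integer(dates - origin) + 1L
    if (!quiet) inform(sprintf("Interpreting `date` as ISO dates; origin %s is day 1.",
                               format(origin)))
  }
  bad_day <- which(!is.na(day) & day < 1)
  if (length(bad_day) > 0) {
    problems <- c(problems, sprintf("line %d: day index %d before the origin",
                                    line[bad_day], day[bad_day]))
  }
  blank <- which(is.na(raw$source) | is.na(raw$target) |
                   raw$source == "" | raw$target == "")
  if (length(blank) > 0) {
    problems <- c(problems, sprintf("line %d: missing source/target", line[blank]))
  }
  if (length(problems) > 0) {
    abort(c("Malformed movement record:", setNames(head(problems, 10), rep("x", min(length(problems), 10)))),
          class = "temponet_error_validation")
  }
  loops <- raw$source == raw$target
  if (any(loops)) {
    if (strict) {
      abort(sprintf("%d self-contact row(s) (source == target).", sum(loops)),
            class = "temponet_error_validation")
    }
    warn(sprintf("Dropping %d self-contact row(s).", sum(loops)))
  }
  ev <- tibble(day = day[!loops], from = raw$source[!loops],
               to = raw$target[!loops])
  ev <- dplyr::arrange(ev, .data$day)
  nodes <- sort(unique(c(ev$from, ev$to)))
  if (!quiet) {
    inform(sprintf("Read %d events between %d nodes over days 1..%d.",
                   nrow(ev), length(nodes), max(ev$day, 0L)))
  }
  attr(ev, "nodes") <- nodes
  attr(ev, "period_length") <- if (nrow(ev) > 0) max(ev$day) else 0L
  ev
}

#' Export a snapshot sequence as a per-window edge list
#'
#' Writes one row per edge with its window index: columns `window_index`,
#' `u`, `v`. Full precision, comma-separated, header included. The file can
#' be round-tripped with [read_snapshots()].
#'
#' @param net A [temporal_network()].
#' @param path Output CSV path.
#' @return The edge-list tibble, invisibly.
#' @export
write_snapshots <- function(net, path) {
  assert_network(net)
  rows <- purrr::imap(net$snapshots, function(s, k) {
    if (nrow(s$edges) == 0) return(NULL)
    tibble(window_index = k, u = s$edges$from, v = s$edges$to)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(window_index = integer(), u = character(),
                                    v = character())
  readr::write_csv(out, path)
  invisible(out)
}

#' Re-read an exported snapshot edge list
#'
#' @param path CSV written by [write_snapshots()].
#' @param n_snapshots Total number of snapshots (needed to restore trailing
#'   edgeless snapshots); defaults to the largest window index present.
#' @param nodes Node universe; defaults to the union of endpoints.
#' @return A [temporal_network()].
#' @export
read_snapshots <- function(path, n_snapshots = NULL, nodes = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(window_index = readr::col_integer(),
                                                .default = readr::col_character()))
  if (!all(c("window_index", "u", "v") %in% names(df))) {
    abort("Snapshot file needs columns window_index, u, v.",
          class = "temponet_error_parameter")
  }
  if (is.null(n_snapshots)) n_snapshots <- max(df$window_index, 1L)
  if (is.null(nodes)) nodes <- sort(unique(c(df$u, df$v)))
  snaps <- lapply(seq_len(n_snapshots), function(k) {
    ed <- df[df$window_index == k, c("u", "v"), drop = FALSE]
    snapshot(ed, nodes = nodes)
  })
  temporal_network(snaps)
}

#' Write a run manifest beside analysis outputs
#'
#' Records the configuration of a run (input, parameters, seed) together
#' with the package version so results can be traced back to their inputs.
#'
#' @param config Named list of configuration values.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  manifest <- c(list(package = "temponet",
                     version = as.character(utils::packageVersion("temponet")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
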