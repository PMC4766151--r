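#' Assemble snapshots into a temporal network
#'
#' A temporal network is an ordered sequence of M snapshots sharing a single
#' node universe of size N. The shared universe is what makes the three
#' overlap normalisations comparable across the sequence.
#'
#' @param snapshots A list of [snapshot()] objects with identical node
#'   universes (same nodes in the same order).
#' @return A `tn_network` object.
#' @examples
#' net <- build_fixture("example1")
#' glance(net)
#' @export
temporal_network <- function(snapshots) {
  if (!is.list(snapshots) || length(snapshots) < 1 ||
      !all(vapply(snapshots, is_snapshot, logical(1)))) {
    abort("`snapshots` must be a nonempty list of tn_snapshot objects.",
          class = "temponet_error_parameter")
  }
  universe <- snapshots[[1]]$nodes
  same <- vapply(snapshots, function(s) identical(s$nodes, universe), logical(1))
  if (!all(same)) {
    abort("All snapshots must share one node universe.",
          class = "temponet_error_validation")
  }
  structure(list(snapshots = snapshots, nodes = universe),
            class = "tn_network")
}

is_network <- function(x) inherits(x, "tn_network")

assert_network <- function(x, min_len = 1L, arg = "net") {
  if (!is_network(x)) {
    abort(sprintf("`%s` must be a tn_network object.", arg),
          class = "temponet_error_parameter")
  }
  if (n_snapshots(x) < min_len) {
    abort(sprintf("`%s` needs at least %d snapshots.", arg, min_len),
          class = "temponet_error_parameter")
  }
  invisible(x)
}

#' @export
print.tn_network <- function(x, ...) {
  cat(sprintf("<tn_network> M = %d snapshots over N = %d nodes\n",
              n_snapshots(x), length(x$nodes)))
  edges <- vapply(x$snapshots, function(s) nrow(s$edges), integer(1))
  cat("  edges per snapshot:", paste(head(edges, 10), collapse = " "),
      if (length(edges) > 10) "..." else "", "\n")
  invisible(x)
}

#' Number of snapshots in a temporal network
#' @param net A [temporal_network()].
#' @return Integer M.
#' @export
n_snapshots <- function(net) length(net$snapshots)

#' Per-snapshot summary of a temporal network
#'
#' @param x A [temporal_network()].
#' @param ... Unused.
#' @return A tibble with one row per snapshot: index `t`, `n_edges`,
#'   `n_active` (active-node count) and `largest_component`.
#' @method tidy tn_network
#' @export
tidy.tn_network <- function(x, ...) {
  tibble(
    t = seq_len(n_snapshots(x)),
    n_edges = vapply(x$snapshots, function(s) nrow(s$edges), integer(1)),
    n_active = vapply(x$snapshots, active_node_count, integer(1)),
    largest_component = vapply(x$snapshots, largest_component_size, integer(1))
  )
}

#' One-row summary of a temporal network
#'
#' @param x A [temporal_network()].
#' @param ... Unused.
#' @return A tibble with columns `n_nodes`, `n_snapshots`, `n_pairs`
#'   (consecutive pairs), `total_edges`.
#' @method glance tn_network
#' @export
glance.tn_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    n_snapshots = n_snapshots(x),
    n_pairs = max(n_snapshots(x) - 1L, 0L),
    total_edges = sum(vapply(x$snapshots, function(s) nrow(s$edges), integer(1)))
  )
}

check_events <- function(events) {
  events <- as_tibble(events)
  need <- c("day", "from", "to")
  if (!all(need %in% names(events))) {
    abort("`events` must have columns `day`, `from`, `to`.",
          class = "temponet_error_parameter")
  }
  if (nrow(events) > 0 && any(events$day < 1)) {
    abort("Event days must be >= 1.", class = "temponet_error_validation")
  }
  events$from <- as.character(events$from)
  events$to <- as.character(events$to)
  events
}

#' Aggregate time-stamped contact events into a snapshot sequence
#'
#' Partitions the observation period into consecutive, non-overlapping time
#' windows of `window_length` days starting at day 1, and builds one snapshot
#' per complete window: window k spans days `[(k-1)*w + 1, k*w]` and contains
#' an edge between two nodes iff at least one event links them inside the
#' window. A trailing incomplete window (when `window_length` does not divide
#' the period) contributes no snapshot. Repeated contacts within a window
#' collapse to a single unweighted edge.
#'
#' @param events Data frame of contact events with columns `day` (integer day
#'   index, 1-based), `from`, `to`. Extra columns are ignored. See
#'   [read_events()] for building this from a movement-record CSV.
#' @param window_length Window length in days (>= 1, <= `period_length`).
#' @param period_length Observation period in days; defaults to the largest
#'   event day. Events beyond it are an error.
#' @param nodes Node universe; defaults to the union of all endpoints over
#'   the whole record. The universe is held constant across all snapshots.
#' @param directed Keep edge direction (default `FALSE`, symmetrised).
#'
#' @return A [temporal_network()] with `floor(period_length / window_length)`
#'   snapshots.
#' @examples
#' ev <- data.frame(day = c(1, 2, 5), from = c("a", "b", "a"), to = c("b", "c", "c"))
#' net <- aggregate_windows(ev, window_length = 2, period_length = 6)
#' n_snapshots(net)
#' @export
aggregate_windows <- function(events, window_length, period_length = NULL,
                              nodes = NULL, directed = FALSE) {
  events <- check_events(events)
  if (is.null(period_length)) {
    period_length <- if (nrow(events) > 0) max(events$day) else
      abort("`period_length` is required when `events` is empty.",
            class = "temponet_error_parameter")
  }
  window_length <- as.integer(window_length)
  period_length <- as.integer(period_length)
  if (is.na(window_length) || window_length < 1 || window_length > period_length) {
    abort("`window_length` must satisfy 1 <= window_length <= period_length.",
          class = "temponet_error_parameter")
  }
  if (nrow(events) > 0 && any(events$day > period_length)) {
    abort("Events found beyond `period_length`.",
          class = "temponet_error_validation")
  }
  if (is.null(nodes)) nodes <- sort(unique(c(events$from, events$to)))
  nodes <- as.character(nodes)
  if (length(nodes) == 0) {
    abort("Empty node universe: supply `nodes` or nonempty `events`.",
          class = "temponet_error_parameter")
  }
  bad <- setdiff(unique(c(events$from, events$to)), nodes)
  if (length(bad) > 0) {
    abort(sprintf("Events reference nodes outside the universe: %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "temponet_error_validation")
  }
  n_windows <- period_length %/% window_length
  window_of <- (events$day - 1L) %/% window_length + 1L
  keep <- window_of <= n_windows   # trailing incomplete window dropped
  events <- events[keep, , drop = FALSE]
  window_of <- window_of[keep]
  snaps <- lapply(seq_len(n_windows), function(k) {
    ed <- events[window_of == k, c("from", "to"), drop = FALSE]
    snapshot(ed, nodes = nodes, directed = directed)
  })
  temporal_network(snaps)
}

#' Extend a temporal network by repeating its last snapshot
#'
#' Appends identical copies of the final snapshot until the sequence reaches
#' `target_length`. This is the construction behind the convergence
#' experiment: every appended consecutive pair is a pair of identical graphs,
#' so a well-behaved overlap normalisation should score it 1.
#'
#' @param net A [temporal_network()].
#' @param target_length Desired number of snapshots (>= current M).
#' @return A [temporal_network()] of length `target_length`.
#' @export
extend_with_last <- function(net, target_length) {
  assert_network(net, min_len = 1L)
  target_length <- as.integer(target_length)
  m <- n_snapshots(net)
  if (is.na(target_length) || target_length < m) {
    abort("`target_length` must be >= the current number of snapshots.",
          class = "temponet_error_parameter")
  }
  if (target_length == m) return(net)
  extra <- rep(net$snapshots[m], target_length - m)
  temporal_network(c(net$snapshots, extra))
}
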