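#' Convergence of the temporal correlation coefficient under identical tails
#'
#' Repeatedly appends copies of the last snapshot (see [extend_with_last()])
#' and records the temporal correlation coefficient of the extended series at
#' every length from the original M up to `target_length`. Each appended
#' consecutive pair is a pair of identical snapshots, so its active-node
#' overlap is exactly 1 (whenever the last snapshot has an edge) and the
#' active-node curve converges to 1. The all-nodes overlap of an appended
#' pair equals the fraction of active nodes in the last snapshot, which is
#' therefore that curve's limit; the component-normalised curve can sit
#' above 1.
#'
#' @param net A [temporal_network()] with at least two snapshots.
#' @param target_length Final series length (default 100).
#' @param undefined Policy for undefined pairs, as in
#'   [temporal_correlation()].
#' @return A tibble of class `tn_convergence` in long form: `length`,
#'   `method`, `C`, plus the per-method overlap of an appended identical
#'   pair in `appended_overlap`.
#' @examples
#' curve <- convergence_curve(build_fixture("example2"), target_length = 100)
#' dplyr::filter(curve, length == 100)
#' @export
convergence_curve <- function(net, target_length = 100,
                              undefined = c("skip", "zero", "error")) {
  undefined <- rlang::arg_match(undefined)
  assert_network(net, min_len = 2L)
  target_length <- as.integer(target_length)
  m <- n_snapshots(net)
  if (is.na(target_length) || target_length < m) {
    abort("`target_length` must be >= the current number of snapshots.",
          class = "temponet_error_parameter")
  }
  series <- overlap_series(net)
  last <- net$snapshots[[m]]
  appended <- vapply(overlap_methods(),
                     function(mth) step_overlap(last, last, mth), numeric(1))
  rows <- purrr::map(overlap_methods(), function(mth) {
    orig <- series[[mth]]
    app <- appended[[mth]]
    cs <- purrr::map_dbl(seq(m, target_length), function(len) {
      vals <- c(orig, rep(app, len - m))
      if (anyNA(vals)) {
        if (undefined == "error") {
          abort("Undefined (0/0) pair in convergence series.",
                class = "temponet_error_undefined")
        }
        if (undefined == "zero") vals[is.na(vals)] <- 0
        else vals <- vals[!is.na(vals)]
      }
      if (length(vals) == 0) NA_real_ else mean(vals)
    })
    tibble(length = seq(m, target_length), method = mth, C = cs,
           appended_overlap = app)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tn_convergence", class(out))
  out
}

#' Number of consecutive-pair observations in a window-length sweep
#'
#' A period of `period_length` days cut into windows of length `w` yields
#' `floor(period_length / w)` snapshots and hence
#' `floor(period_length / w) - 1` consecutive pairs. This sums that count
#' over a range of window lengths — the total number of overlap
#' observations a full sweep produces. Window lengths yielding fewer than
#' two snapshots contribute nothing.
#'
#' @param period_length Observation period in days.
#' @param w_min,w_max Range of window lengths (inclusive).
#' @return Integer total pair count.
#' @examples
#' count_sweep_pairs(1096, 1, 548)  # 6749
#' @export
count_sweep_pairs <- function(period_length, w_min, w_max) {
  w <- seq(as.integer(w_min), as.integer(w_max))
  counts <- as.integer(period_length) %/% w - 1L
  sum(pmax(counts, 0L))
}

#' Sweep the time-window length over an event record
#'
#' For each window length in `[w_min, w_max]`, aggregates the events into a
#' snapshot sequence ([aggregate_windows()]), computes the full overlap
#' series, the temporal correlation coefficient under all three methods, and
#' the per-pair covariates. Window lengths yielding fewer than two snapshots
#' are skipped with a warning. A shared node universe (the union of all
#' endpoints, unless given) is used for every window length, so N is
#' constant across the sweep.
#'
#' @inheritParams aggregate_windows
#' @param w_min,w_max Range of window lengths to sweep (inclusive).
#' @param undefined Policy for undefined pairs, as in
#'   [temporal_correlation()].
#' @return A tibble of class `tn_sweep` with one row per window length:
#'   `window_length`, `n_snapshots`, `n_pairs`, `c_method1`, `c_method2`,
#'   `c_method3`, `n_undefined3`, and list-columns `overlap`
#'   ([overlap_series()] tibble) and `characteristics`
#'   ([characteristics_series()] tibble). The grand total of pairs is
#'   `sum(result$n_pairs)`.
#' @export
sweep_window_lengths <- function(events, period_length, w_min = 1, w_max,
                                 nodes = NULL, directed = FALSE,
                                 undefined = c("skip", "zero", "error")) {
  undefined <- rlang::arg_match(undefined)
  events <- check_events(events)
  if (is.null(nodes)) nodes <- sort(unique(c(events$from, events$to)))
  w_min <- as.integer(w_min)
  w_max <- as.integer(w_max)
  if (w_min < 1 || w_max < w_min || w_max > period_length) {
    abort("Need 1 <= w_min <= w_max <= period_length.",
          class = "temponet_error_parameter")
  }
  rows <- purrr::map(seq(w_min, w_max), function(w) {
    n_snap <- period_length %/% w
    if (n_snap < 2) {
      warn(sprintf("Window length %d yields %d snapshot(s); skipped.", w, n_snap))
      return(NULL)
    }
    net <- aggregate_windows(events, w, period_length, nodes = nodes,
                             directed = directed)
    series <- overlap_series(net)
    chars <- characteristics_series(net, twl = w)
    cval <- function(mth) {
      vals <- series[[mth]]
      if (undefined == "zero") vals[is.na(vals)] <- 0
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) NA_real_ else mean(vals)
    }
    if (undefined == "error" && any(!series$defined3)) {
      abort(sprintf("Undefined (0/0) pair at window length %d.", w),
            class = "temponet_error_undefined")
    }
    tibble(
      window_length = w,
      n_snapshots = n_snap,
      n_pairs = n_snap - 1L,
      c_method1 = cval("method1"),
      c_method2 = cval("method2"),
      c_method3 = cval("method3"),
      n_undefined3 = sum(!series$defined3),
      overlap = list(series),
      characteristics = list(chars)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tn_sweep", class(out))
  out
}
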