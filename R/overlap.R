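#' The three overlap normalisation methods
#'
#' `overlap_methods()` returns the closed set of method names used throughout
#' the package:
#' * `method1` — divide the summed node overlaps by N, the total number of
#'   nodes. Underestimates persistence when isolated nodes are present.
#' * `method2` — divide by the maximal largest-connected-component size of
#'   the two snapshots. Can exceed 1 when more nodes are active than sit in
#'   the largest component.
#' * `method3` — divide by the maximal active-node count of the two
#'   snapshots. Stays in `[0, 1]` and equals 1 for identical nonempty
#'   snapshots; undefined (0/0) only when both snapshots are edgeless.
#'
#' @return Character vector `c("method1", "method2", "method3")`.
#' @export
overlap_methods <- function() c("method1", "method2", "method3")

# Row-sets of the adjacency matrix: out-neighbours when directed.
adjacency_sets <- function(s) {
  if (!s$directed) return(neighbour_sets(s))
  nb <- setNames(vector("list", length(s$nodes)), s$nodes)
  for (i in seq_along(nb)) nb[[i]] <- character()
  if (nrow(s$edges) > 0) {
    sp <- split(s$edges$to, s$edges$from)
    for (n in names(sp)) nb[[n]] <- unique(sp[[n]])
  }
  nb
}

assert_same_universe <- function(a, b) {
  assert_snapshot(a, "a")
  assert_snapshot(b, "b")
  if (!identical(a$nodes, b$nodes)) {
    abort("Snapshots must share one node universe.",
          class = "temponet_error_validation")
  }
  invisible(NULL)
}

node_overlap_one <- function(na, nb) {
  da <- length(na)
  db <- length(nb)
  if (da == 0 || db == 0) return(0)  # inactive in either snapshot: defined as 0
  length(intersect(na, nb)) / sqrt(da * db)
}

#' Topological overlap of one node's neighbourhood across two snapshots
#'
#' The cosine-type similarity of node `i`'s neighbour sets in two consecutive
#' snapshots: the number of neighbours shared by both, divided by the
#' geometric mean of the two degrees. A node inactive in either snapshot
#' scores 0 (the 0/0 case is defined as 0, so two graphs sharing no edges
#' get a summed overlap of 0).
#'
#' @param a,b Two [snapshot()]s over the same node universe.
#' @param i Node identifier (coerced to character).
#' @return A number in `[0, 1]`; exactly 1 iff the neighbourhoods are
#'   identical and nonempty.
#' @examples
#' net <- build_fixture("example1")
#' node_overlap(net$snapshots[[1]], net$snapshots[[2]], "1")  # 1/sqrt(3)
#' @export
node_overlap <- function(a, b, i) {
  assert_same_universe(a, b)
  i <- as.character(i)
  if (!i %in% a$nodes) {
    abort(sprintf("Unknown node '%s'.", i), class = "temponet_error_validation")
  }
  node_overlap_one(adjacency_sets(a)[[i]], adjacency_sets(b)[[i]])
}

# Summed node overlaps plus the three normalisers for one pair.
pair_overlap_raw <- function(a, b) {
  na <- adjacency_sets(a)
  nb <- adjacency_sets(b)
  # Only nodes active in both snapshots can contribute a nonzero term.
  both <- intersect(unique(c(a$edges$from, a$edges$to)),
                    unique(c(b$edges$from, b$edges$to)))
  raw <- sum(vapply(both, function(i) node_overlap_one(na[[i]], nb[[i]]),
                    numeric(1)))
  list(
    raw_sum = raw,
    norm1 = length(a$nodes),
    norm2 = max(largest_component_size(a), largest_component_size(b)),
    norm3 = max(active_node_count(a), active_node_count(b))
  )
}

#' Average topological overlap of a consecutive snapshot pair
#'
#' Sums the node-level overlaps over all nodes and divides by the method's
#' normaliser: N (`method1`), the maximal largest-component size (`method2`)
#' or the maximal active-node count (`method3`). With both snapshots
#' edgeless, `method3` is 0/0 and returns `NA`; `method2` returns 0 under the
#' singleton-component convention (largest component size 1); `method1` is
#' always defined for a nonempty universe.
#'
#' @param a,b Two [snapshot()]s over the same node universe.
#' @param method One of [overlap_methods()].
#' @return A single number (possibly `NA` for the undefined `method3` case).
#'   `method1` and `method3` values lie in `[0, 1]`; `method2` can exceed 1.
#' @examples
#' net <- build_fixture("example2")
#' step_overlap(net$snapshots[[2]], net$snapshots[[3]], "method1")  # 0.8
#' step_overlap(net$snapshots[[2]], net$snapshots[[3]], "method3")  # 1
#' @export
step_overlap <- function(a, b, method = overlap_methods()) {
  method <- rlang::arg_match(method)
  assert_same_universe(a, b)
  if (length(a$nodes) < 1) {
    abort("Need a nonempty node universe.", class = "temponet_error_parameter")
  }
  p <- pair_overlap_raw(a, b)
  norm <- switch(method, method1 = p$norm1, method2 = p$norm2, method3 = p$norm3)
  if (norm == 0) return(NA_real_)
  p$raw_sum / norm
}

#' Per-pair overlap records for a whole snapshot sequence
#'
#' Computes, for every consecutive snapshot pair, the summed node overlaps,
#' the three normalisers, and the average topological overlap under all
#' three methods in one pass.
#'
#' @param net A [temporal_network()] with at least two snapshots.
#' @return A tibble of class `tn_overlap_series` with one row per pair:
#'   `m` (pair index), `raw_sum`, `norm_method1` (N), `norm_method2`
#'   (max largest-component size), `norm_method3` (max active-node count),
#'   `method1`, `method2`, `method3` (the per-pair overlaps; `method3` is
#'   `NA` where both snapshots are edgeless) and `defined3`.
#' @examples
#' overlap_series(build_fixture("example3"))
#' @export
overlap_series <- function(net) {
  assert_network(net, min_len = 2L)
  m <- n_snapshots(net)
  rows <- purrr::map(seq_len(m - 1L), function(k) {
    p <- pair_overlap_raw(net$snapshots[[k]], net$snapshots[[k + 1L]])
    tibble(
      m = k,
      raw_sum = p$raw_sum,
      norm_method1 = p$norm1,
      norm_method2 = p$norm2,
      norm_method3 = p$norm3,
      method1 = p$raw_sum / p$norm1,
      method2 = if (p$norm2 > 0) p$raw_sum / p$norm2 else NA_real_,
      method3 = if (p$norm3 > 0) p$raw_sum / p$norm3 else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  out$defined3 <- !is.na(out$method3)
  class(out) <- c("tn_overlap_series", class(out))
  out
}

#' Temporal correlation coefficient
#'
#' The mean of the average topological overlap over all M-1 consecutive
#' snapshot pairs — interpreted as the average probability for an edge to
#' persist from one snapshot to the next. With `method3`, pairs of edgeless
#' snapshots are 0/0 and handled by `undefined`: `"skip"` (default) excludes
#' them from numerator and denominator and reports their count via a message,
#' `"zero"` counts them as 0, `"error"` raises.
#'
#' @param net A [temporal_network()] with at least two snapshots.
#' @param method One of [overlap_methods()].
#' @param undefined Policy for undefined (0/0) pairs: `"skip"`, `"zero"`, or
#'   `"error"`.
#' @param quiet Suppress the skipped-pair message.
#' @return A single number. `method1`/`method3` values lie in `[0, 1]`;
#'   `method2` can exceed 1.
#' @examples
#' net <- build_fixture("example2")
#' temporal_correlation(net, "method3")  # ~0.70
#' @export
temporal_correlation <- function(net, method = overlap_methods(),
                                 undefined = c("skip", "zero", "error"),
                                 quiet = FALSE) {
  method <- rlang::arg_match(method)
  undefined <- rlang::arg_match(undefined)
  assert_network(net, min_len = 2L)
  series <- overlap_series(net)
  vals <- series[[method]]
  n_undef <- sum(is.na(vals))
  if (n_undef > 0) {
    if (undefined == "error") {
      abort(sprintf("%d undefined (0/0) pair(s) under %s.", n_undef, method),
            class = "temponet_error_undefined")
    }
    if (undefined == "zero") {
      vals[is.na(vals)] <- 0
    } else {
      if (!quiet) {
        inform(sprintf("Skipping %d undefined (0/0) pair(s) under %s.",
                       n_undef, method))
      }
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) {
        abort("All pairs are undefined; no temporal correlation available.",
              class = "temponet_error_undefined")
      }
    }
  }
  mean(vals)
}
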