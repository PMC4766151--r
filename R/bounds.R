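#' Per-pair distortion ratios between overlap methods
#'
#' For each consecutive pair, the ratio of the all-nodes overlap to the
#' component-normalised overlap equals the normaliser quotient
#' `max[N(t_m), N(t_{m+1})] / N` exactly, and likewise the ratio to the
#' active-node overlap equals `max[A(t_m), A(t_{m+1})] / N`. Both the value
#' quotient and the closed-form normaliser quotient are returned; they agree
#' exactly whenever the denominator overlap is nonzero (this identity is the
#' module's core invariant). Ratios quantify by how much the all-nodes
#' normalisation underestimates edge persistence on that pair.
#'
#' @param net A [temporal_network()] with at least two snapshots.
#' @return A tibble with one row per pair: `m`, `r12`, `r13` (value
#'   quotients, `NA` where the denominator overlap is 0 or undefined),
#'   `r12_normaliser`, `r13_normaliser` (the closed forms, always defined).
#' @export
pairwise_ratios <- function(net) {
  assert_network(net, min_len = 2L)
  s <- overlap_series(net)
  tibble(
    m = s$m,
    r12 = ifelse(!is.na(s$method2) & s$method2 != 0, s$method1 / s$method2, NA_real_),
    r13 = ifelse(!is.na(s$method3) & s$method3 != 0, s$method1 / s$method3, NA_real_),
    r12_normaliser = s$norm_method2 / s$norm_method1,
    r13_normaliser = s$norm_method3 / s$norm_method1
  )
}

#' Average underestimation of the all-nodes normalisation
#'
#' The mean over consecutive pairs of the normaliser quotient — the mean of
#' `max[N(t_m), N(t_{m+1})] / N` (against the component-normalised method)
#' or of `max[A(t_m), A(t_{m+1})] / N` (against the active-node method).
#' This is the averaged factor by which the all-nodes normalisation
#' understates the topological overlap over the whole sequence; it always
#' lies in `(0, 1]`.
#'
#' @param net A [temporal_network()] with at least two snapshots.
#' @param vs Compare against `"method2"` (largest-component normaliser) or
#'   `"method3"` (active-node normaliser).
#' @return A single number in `(0, 1]`.
#' @examples
#' averaged_underestimation(build_fixture("example2"), vs = "method2")  # 0.6
#' @export
averaged_underestimation <- function(net, vs = c("method2", "method3")) {
  vs <- rlang::arg_match(vs)
  assert_network(net, min_len = 2L)
  s <- overlap_series(net)
  col <- if (vs == "method2") s$norm_method2 else s$norm_method3
  mean(col / s$norm_method1)
}

# Global minimum of node overlaps over all pairs; min_over = "active"
# restricts to nodes active in both snapshots of each pair.
min_node_overlap <- function(net, min_over = c("all", "active")) {
  min_over <- rlang::arg_match(min_over)
  m <- n_snapshots(net)
  mins <- purrr::map_dbl(seq_len(m - 1L), function(k) {
    a <- net$snapshots[[k]]
    b <- net$snapshots[[k + 1L]]
    na <- adjacency_sets(a)
    nb <- adjacency_sets(b)
    idx <- if (min_over == "active") {
      intersect(unique(c(a$edges$from, a$edges$to)),
                unique(c(b$edges$from, b$edges$to)))
    } else {
      a$nodes
    }
    if (length(idx) == 0) return(NA_real_)
    min(vapply(idx, function(i) node_overlap_one(na[[i]], nb[[i]]), numeric(1)))
  })
  mins <- mins[!is.na(mins)]
  if (length(mins) == 0) NA_real_ else min(mins)
}

#' Analytic distortion bounds between temporal correlation coefficients
#'
#' Computes the observed quotients between the three temporal correlation
#' coefficients together with their analytic lower and upper boundaries.
#' Writing `N(t)` for the largest-component size and `A(t)` for the
#' active-node count of snapshot `t`, and `minC` for the global minimum of
#' node overlaps over all nodes and consecutive pairs, the bounds are
#' \deqn{min_m(max[N(t_m), N(t_{m+1})]) minC / N \le C^1/C^2 \le
#'       max_m(N(t_m)) / (N minC)}
#' with the analogous forms for `C^1/C^3` (using `A`) and `C^2/C^3` (mixing
#' `A` and `N`). When `minC = 0` the upper bounds degenerate to `Inf` and
#' the lower bounds to 0; because the minimum runs over all nodes including
#' inactive ones, this is the typical outcome on sparse networks. Set
#' `min_over = "active"` to take the minimum only over nodes active in both
#' snapshots of each pair, which often gives informative bounds.
#'
#' @param net A [temporal_network()] with at least two snapshots.
#' @param min_over Index set for `minC`: `"all"` nodes (the literal
#'   definition, default) or `"active"` in both snapshots of each pair.
#' @param undefined Policy for undefined pairs passed to
#'   [temporal_correlation()].
#' @return An object of class `tn_distortion`: see [tidy.tn_distortion()]
#'   and [glance.tn_distortion()]. Quotients with a zero denominator are
#'   `NA` and flagged.
#' @examples
#' rep <- correlation_bounds(build_fixture("example1"))
#' tidy(rep)
#' @export
correlation_bounds <- function(net, min_over = c("all", "active"),
                               undefined = "skip") {
  min_over <- rlang::arg_match(min_over)
  assert_network(net, min_len = 2L)
  s <- overlap_series(net)
  n_total <- length(net$nodes)
  firsts <- vapply(net$snapshots, largest_component_size, integer(1))
  actives <- vapply(net$snapshots, active_node_count, integer(1))
  min_max_n <- min(s$norm_method2)   # min over pairs of max[N(t_m), N(t_m+1)]
  min_max_a <- min(s$norm_method3)
  max_n <- max(firsts)
  max_a <- max(actives)
  minc <- min_node_overlap(net, min_over)

  cvals <- purrr::map_dbl(setNames(overlap_methods(), overlap_methods()),
                          function(mth) {
    tryCatch(temporal_correlation(net, mth, undefined = undefined, quiet = TRUE),
             temponet_error_undefined = function(e) NA_real_)
  })
  quo <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  bound <- function(lower_num, upper_num) {
    if (is.na(minc)) return(c(lower = NA_real_, upper = NA_real_))
    c(lower = if (minc > 0) lower_num * minc else 0,
      upper = if (minc > 0) upper_num / minc else Inf)
  }
  b12 <- bound(min_max_n / n_total, max_n / n_total)
  b13 <- bound(min_max_a / n_total, max_a / n_total)
  b23 <- bound(min_max_a / max_n, max_a / min_max_n)
  structure(list(
    min_c = minc,
    min_over = min_over,
    n_nodes = n_total,
    c_values = cvals,
    bounds = tibble(
      comparison = c("C1/C2", "C1/C3", "C2/C3"),
      lower = unname(c(b12["lower"], b13["lower"], b23["lower"])),
      observed = c(quo(cvals[["method1"]], cvals[["method2"]]),
                   quo(cvals[["method1"]], cvals[["method3"]]),
                   quo(cvals[["method2"]], cvals[["method3"]])),
      upper = unname(c(b12["upper"], b13["upper"], b23["upper"]))
    )
  ), class = "tn_distortion")
}

#' @export
print.tn_distortion <- function(x, ...) {
  cat(sprintf("<tn_distortion> minC = %s (over %s nodes), N = %d\n",
              format(round(x$min_c, 4)), x$min_over, x$n_nodes))
  cat(sprintf("  C: method1 = %.2f, method2 = %.2f, method3 = %.2f\n",
              x$c_values[["method1"]], x$c_values[["method2"]],
              x$c_values[["method3"]]))
  b <- x$bounds
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %s: %.4g <= %.4g <= %.4g\n", b$comparison[i],
                b$lower[i], b$observed[i], b$upper[i]))
  }
  invisible(x)
}

#' Tidy a distortion report
#'
#' @param x A [correlation_bounds()] result.
#' @param ... Unused.
#' @return A tibble with one row per method comparison: `comparison`,
#'   `lower`, `observed`, `upper`, and `within_bounds` (`NA` where a bound
#'   or quotient is undefined).
#' @method tidy tn_distortion
#' @export
tidy.tn_distortion <- function(x, ...) {
  dplyr::mutate(
    x$bounds,
    within_bounds = .data$lower <= .data$observed & .data$observed <= .data$upper
  )
}

#' One-row summary of a distortion report
#'
#' @param x A [correlation_bounds()] result.
#' @param ... Unused.
#' @return A tibble with `min_c`, `min_over`, the three temporal correlation
#'   coefficients, and `all_within_bounds`.
#' @method glance tn_distortion
#' @export
glance.tn_distortion <- function(x, ...) {
  td <- tidy(x)
  tibble(
    min_c = x$min_c,
    min_over = x$min_over,
    c_method1 = x$c_values[["method1"]],
    c_method2 = x$c_values[["method2"]],
    c_method3 = x$c_values[["method3"]],
    all_within_bounds = all(td$within_bounds, na.rm = TRUE)
  )
}
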