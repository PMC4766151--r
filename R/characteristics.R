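snapshot_characteristics <- function(s) {
  census <- component_census(s)
  multi <- census[census > 1]
  list(
    n_multi = length(multi),
    mean_multi_size = if (length(multi) > 0) mean(multi) else 0,
    n_edges = nrow(s$edges),
    first = max(census),
    active_first = active_node_count(s) - max(census)
  )
}

#' Network covariates for one consecutive snapshot pair
#'
#' Computes the pairwise structural covariates used to characterise a
#' consecutive snapshot pair; each is the arithmetic mean of a per-snapshot
#' quantity over the two snapshots:
#' * `mean_number` — number of connected components containing more than one
#'   node;
#' * `mean_size` — average size of those multi-node components (0 for a
#'   snapshot with none, so sweeps over sparse records never fail);
#' * `mean_edges` — edge count;
#' * `mean_first` — size of the largest connected component;
#' * `mean_active_first` — active-node count minus largest-component size
#'   (the surplus of active nodes outside the largest component).
#'
#' @param a,b Two [snapshot()]s over the same node universe.
#' @param twl Time-window length (days) used to build the snapshots; carried
#'   through as a covariate.
#' @return A one-row tibble with columns `twl`, `mean_number`, `mean_size`,
#'   `mean_edges`, `mean_first`, `mean_active_first`.
#' @examples
#' net <- build_fixture("example2")
#' pair_characteristics(net$snapshots[[2]], net$snapshots[[3]], twl = 1)
#' @export
pair_characteristics <- function(a, b, twl = NA_integer_) {
  assert_same_universe(a, b)
  ca <- snapshot_characteristics(a)
  cb <- snapshot_characteristics(b)
  tibble(
    twl = as.integer(twl),
    mean_number = (ca$n_multi + cb$n_multi) / 2,
    mean_size = (ca$mean_multi_size + cb$mean_multi_size) / 2,
    mean_edges = (ca$n_edges + cb$n_edges) / 2,
    mean_first = (ca$first + cb$first) / 2,
    mean_active_first = (ca$active_first + cb$active_first) / 2
  )
}

#' Pair covariates for every consecutive pair of a snapshot sequence
#'
#' @param net A [temporal_network()] with at least two snapshots.
#' @param twl Time-window length covariate attached to every row.
#' @return A tibble with one row per consecutive pair (`m` plus the
#'   [pair_characteristics()] columns).
#' @export
characteristics_series <- function(net, twl = NA_integer_) {
  assert_network(net, min_len = 2L)
  m <- n_snapshots(net)
  per_snap <- lapply(net$snapshots, snapshot_characteristics)
  rows <- purrr::map(seq_len(m - 1L), function(k) {
    ca <- per_snap[[k]]
    cb <- per_snap[[k + 1L]]
    tibble(
      m = k,
      twl = as.integer(twl),
      mean_number = (ca$n_multi + cb$n_multi) / 2,
      mean_size = (ca$mean_multi_size + cb$mean_multi_size) / 2,
      mean_edges = (ca$n_edges + cb$n_edges) / 2,
      mean_first = (ca$first + cb$first) / 2,
      mean_active_first = (ca$active_first + cb$active_first) / 2
    )
  })
  dplyr::bind_rows(rows)
}

#' Categorise pair covariates into analysis groups
#'
#' Bins the six pair covariates into the ordered factor levels used when
#' relating network structure to differences between overlap methods. The
#' boundaries are fixed: `twl` into \{1, 2–4, 5–12, 13–35, 36–105, >=106\};
#' `mean_number` into \{<=4, 5–11, >=12\}; `mean_size` into \{<=3, (3,4.5],
#' (4.5,23], >23\}; `mean_edges` into \{<=20, 21–125, >=126\}; `mean_first`
#' into \{<=7, 8–60, >=61\}; `mean_active_first` into \{<=8, 9–35, >=36\}.
#' No model is fitted here; the function only adds the grouping columns.
#'
#' @param df A data frame containing the [pair_characteristics()] columns.
#' @return `df` with additional ordered-factor columns suffixed `_group`.
#' @export
characteristic_groups <- function(df) {
  df <- as_tibble(df)
  cut_grp <- function(x, breaks, labels) {
    cut(x, breaks = breaks, labels = labels, right = TRUE, ordered_result = TRUE)
  }
  dplyr::mutate(
    df,
    twl_group = cut_grp(.data$twl, c(0, 1, 4, 12, 35, 105, Inf),
                        c("1", "2-4", "5-12", "13-35", "36-105", ">=106")),
    mean_number_group = cut_grp(.data$mean_number, c(-Inf, 4, 11, Inf),
                                c("<=4", "5-11", ">=12")),
    mean_size_group = cut_grp(.data$mean_size, c(-Inf, 3, 4.5, 23, Inf),
                              c("<=3", "(3,4.5]", "(4.5,23]", ">23")),
    mean_edges_group = cut_grp(.data$mean_edges, c(-Inf, 20, 125, Inf),
                               c("<=20", "21-125", ">=126")),
    mean_first_group = cut_grp(.data$mean_first, c(-Inf, 7, 60, Inf),
                               c("<=7", "8-60", ">=61")),
    mean_active_first_group = cut_grp(.data$mean_active_first, c(-Inf, 8, 35, Inf),
                                      c("<=8", "9-35", ">=36"))
  )
}

#' Descriptive moment summary of a numeric sample
#'
#' Minimum, maximum, mean, and population (divide-by-n) central moments:
#' variance `m2`, skewness `m3 / m2^(3/2)` and non-excess kurtosis
#' `m4 / m2^2` (a large normal sample scores about 3). Skewness and kurtosis
#' are `NA` when the variance is zero or `n < 2`.
#'
#' @param values Numeric vector, `NA`s dropped; at least one finite value
#'   required.
#' @return A one-row tibble: `n`, `min`, `max`, `mean`, `variance`,
#'   `skewness`, `kurtosis`.
#' @examples
#' moment_summary(c(0, 0, 1, 1))
#' @export
moment_summary <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) {
    abort("`values` must contain at least one non-missing number.",
          class = "temponet_error_parameter")
  }
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  ok <- n >= 2 && m2 > 0
  tibble(
    n = n,
    min = min(values),
    max = max(values),
    mean = mu,
    variance = m2,
    skewness = if (ok) m3 / m2^1.5 else NA_real_,
    kurtosis = if (ok) m4 / m2^2 else NA_real_
  )
}
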