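#' Build a network snapshot over a fixed node universe
#'
#' A snapshot is the static, unweighted, simple graph obtained by aggregating
#' all contacts that fall inside one time window. It always carries the full
#' node universe, so nodes without any edge in the window (isolated nodes)
#' remain part of the graph — this matters because the three overlap
#' normalisations differ precisely in how they treat such nodes.
#'
#' @param edges A data frame (or two-column matrix) of edges with columns
#'   `from` and `to` (the first two columns are used). Duplicate edges are
#'   collapsed; self-loops are dropped with a warning.
#' @param nodes Character vector giving the node universe. Defaults to the
#'   nodes appearing in `edges`. Every edge endpoint must be contained in it.
#' @param directed Keep edge direction? Default `FALSE`: movement records are
#'   directed (supplier to purchaser) but the overlap formula uses a symmetric
#'   unweighted adjacency, so edges are symmetrised by default.
#'
#' @return An object of class `tn_snapshot`: a list with elements `nodes`
#'   (character), `edges` (tibble with columns `from`, `to`, canonicalised and
#'   deduplicated) and `directed`.
#'
#' @examples
#' s <- snapshot(data.frame(from = c(1, 3), to = c(2, 4)), nodes = as.character(1:5))
#' active_node_count(s)
#' largest_component_size(s)
#' @export
snapshot <- function(edges = NULL, nodes = NULL, directed = FALSE) {
  if (is.null(edges)) {
    ed <- tibble(from = character(), to = character())
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2) {
      abort("`edges` needs at least two columns (from, to).",
            class = "temponet_error_parameter")
    }
    ed <- tibble(from = as.character(edges[[1]]), to = as.character(edges[[2]]))
  }
  loops <- ed$from == ed$to
  if (any(loops)) {
    warn(sprintf("Dropping %d self-loop(s); self-contacts carry no overlap information.",
                 sum(loops)))
    ed <- ed[!loops, , drop = FALSE]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(ed$from, ed$to)))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    abort("`nodes` contains duplicates.", class = "temponet_error_validation")
  }
  bad <- setdiff(unique(c(ed$from, ed$to)), nodes)
  if (length(bad) > 0) {
    abort(sprintf("Edge endpoints outside the node universe: %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "temponet_error_validation")
  }
  if (!directed) {
    swap <- ed$from > ed$to
    tmp <- ed$from[swap]
    ed$from[swap] <- ed$to[swap]
    ed$to[swap] <- tmp
  }
  ed <- dplyr::distinct(ed)
  ed <- dplyr::arrange(ed, .data$from, .data$to)
  structure(list(nodes = nodes, edges = ed, directed = directed),
            class = "tn_snapshot")
}

#' @export
print.tn_snapshot <- function(x, ...) {
  cat(sprintf("<tn_snapshot> %d nodes, %d edges (%s), %d active\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              active_node_count(x)))
  invisible(x)
}

#' @export
format.tn_snapshot <- function(x, ...) {
  sprintf("<tn_snapshot: %d nodes, %d edges>", length(x$nodes), nrow(x$edges))
}

is_snapshot <- function(x) inherits(x, "tn_snapshot")

assert_snapshot <- function(x, arg = "snapshot") {
  if (!is_snapshot(x)) {
    abort(sprintf("`%s` must be a tn_snapshot object.", arg),
          class = "temponet_error_parameter")
  }
  invisible(x)
}

#' Convert a snapshot to an igraph graph
#'
#' Isolated nodes are preserved as vertices so component sizes and counts are
#' computed over the full universe.
#'
#' @param s A [snapshot()].
#' @return An `igraph` graph with one vertex per node in the universe.
#' @export
as_igraph <- function(s) {
  assert_snapshot(s)
  igraph::graph_from_data_frame(s$edges, directed = s$directed,
                                vertices = data.frame(name = s$nodes))
}

# Named list: for each node, its (undirected-sense) neighbour set.
neighbour_sets <- function(s) {
  nb <- setNames(vector("list", length(s$nodes)), s$nodes)
  for (i in seq_along(nb)) nb[[i]] <- character()
  if (nrow(s$edges) > 0) {
    sp_from <- split(s$edges$to, s$edges$from)
    sp_to <- split(s$edges$from, s$edges$to)
    for (n in names(sp_from)) nb[[n]] <- c(nb[[n]], sp_from[[n]])
    for (n in names(sp_to)) nb[[n]] <- c(nb[[n]], sp_to[[n]])
    nb <- lapply(nb, unique)
  }
  nb
}

#' Count the active nodes of a snapshot
#'
#' A node is active if it has at least one edge in the snapshot. The maximal
#' active-node count of a consecutive snapshot pair is the normaliser of the
#' active-node overlap method.
#'
#' @param s A [snapshot()].
#' @return Integer in `[0, N]`; 0 exactly when the snapshot has no edges.
#' @export
active_node_count <- function(s) {
  assert_snapshot(s)
  length(unique(c(s$edges$from, s$edges$to)))
}

#' Size of the largest connected component
#'
#' An isolated node is a component of size 1, so an edgeless snapshot on a
#' nonempty universe has largest component size 1. The maximal
#' largest-component size of a consecutive pair is the normaliser of the
#' connected-nodes overlap method.
#'
#' @param s A [snapshot()].
#' @return Integer in `[1, N]`.
#' @export
largest_component_size <- function(s) {
  assert_snapshot(s)
  if (length(s$nodes) == 0) {
    abort("Largest component of an empty node universe is undefined.",
          class = "temponet_error_parameter")
  }
  if (nrow(s$edges) == 0) return(1L)
  max(component_census(s))
}

#' Connected-component size census
#'
#' @param s A [snapshot()].
#' @return Integer vector of component sizes, sorted in decreasing order;
#'   sizes sum to the universe size `N` (isolated nodes count as size-1
#'   components).
#' @export
component_census <- function(s) {
  assert_snapshot(s)
  if (length(s$nodes) == 0) return(integer())
  comp <- igraph::components(as_igraph(s), mode = "weak")
  sort(as.integer(comp$csize), decreasing = TRUE)
}
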