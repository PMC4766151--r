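# Independent oracles and generators used across the suite. These stay
# deliberately naive (flood fill, explicit set arithmetic, direct averaging)
# so they check the package implementation without sharing code with it.

# Erdos-Renyi-style snapshot over a fixed universe.
random_snapshot <- function(n_nodes = 8, p = 0.3, nodes = as.character(seq_len(n_nodes))) {
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  snapshot(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]), nodes = nodes)
}

# Flood-fill connected components; returns sizes sorted decreasing.
bfs_component_sizes <- function(s) {
  adj <- lapply(setNames(s$nodes, s$nodes), function(n) character())
  for (k in seq_len(nrow(s$edges))) {
    u <- s$edges$from[k]; v <- s$edges$to[k]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  unseen <- s$nodes
  sizes <- integer()
  while (length(unseen) > 0) {
    queue <- unseen[1]
    comp <- character()
    while (length(queue) > 0) {
      node <- queue[1]; queue <- queue[-1]
      if (node %in% comp) next
      comp <- c(comp, node)
      queue <- c(queue, setdiff(adj[[node]], comp))
    }
    sizes <- c(sizes, length(comp))
    unseen <- setdiff(unseen, comp)
  }
  sort(sizes, decreasing = TRUE)
}

# Neighbour-set formulation of the node overlap.
set_overlap_oracle <- function(a, b, i) {
  nbrs <- function(s, i) {
    unique(c(s$edges$to[s$edges$from == i], s$edges$from[s$edges$to == i]))
  }
  na <- nbrs(a, i); nb <- nbrs(b, i)
  if (length(na) == 0 || length(nb) == 0) return(0)
  length(intersect(na, nb)) / sqrt(length(na) * length(nb))
}

# Summed node overlaps over the whole universe, via the oracle.
raw_sum_oracle <- function(a, b) {
  sum(vapply(a$nodes, function(i) set_overlap_oracle(a, b, i), numeric(1)))
}

fixture_ids <- c("example1", "example2", "example3")
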