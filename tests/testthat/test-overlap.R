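test_that("node overlap reproduces the worked per-node values of example network 1", {
  net <- build_fixture("example1")
  a <- net$snapshots[[1]]; b <- net$snapshots[[2]]
  expect_equal(node_overlap(a, b, "1"), 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(node_overlap(a, b, "2"), 1)
  expect_equal(node_overlap(a, b, "3"), 0)
  expect_equal(node_overlap(a, b, "4"), 0)
  expect_error(node_overlap(a, b, "99"), class = "temponet_error_validation")
})

test_that("node overlap is 1 for identical nonempty neighbourhoods and 0 for isolated nodes", {
  s <- snapshot(data.frame(from = "a", to = "b"), nodes = c("a", "b", "c"))
  expect_equal(node_overlap(s, s, "a"), 1)
  expect_equal(node_overlap(s, s, "c"), 0)
})

test_that("node overlap equals the neighbour-set oracle on random snapshot pairs", {
  set.seed(101)
  for (rep in 1:30) {
    a <- random_snapshot(n_nodes = 9, p = 0.3)
    b <- random_snapshot(n_nodes = 9, p = 0.3)
    for (i in a$nodes) {
      expect_equal(node_overlap(a, b, i), set_overlap_oracle(a, b, i),
                   tolerance = 1e-12)
    }
  }
})

test_that("step overlap reproduces the worked per-pair values of example networks 2 and 3", {
  net2 <- build_fixture("example2")
  a <- net2$snapshots[[2]]; b <- net2$snapshots[[3]]
  expect_equal(step_overlap(a, b, "method1"), 0.80)
  expect_equal(step_overlap(a, b, "method2"), 2)
  expect_equal(step_overlap(a, b, "method3"), 1)

  net3 <- build_fixture("example3")
  a <- net3$snapshots[[1]]; b <- net3$snapshots[[2]]
  expect_equal(round(step_overlap(a, b, "method1"), 2), 0.23)
  expect_equal(round(step_overlap(a, b, "method2"), 2), 0.39)
  expect_equal(round(step_overlap(a, b, "method3"), 2), 0.32)
})

test_that("step overlap handles edgeless pairs per convention: method3 undefined, method2 zero", {
  empty <- snapshot(nodes = as.character(1:4))
  expect_true(is.na(step_overlap(empty, empty, "method3")))
  expect_equal(step_overlap(empty, empty, "method2"), 0)
  expect_equal(step_overlap(empty, empty, "method1"), 0)
})

test_that("step overlap is symmetric in its two snapshots and validates universes", {
  set.seed(5)
  for (rep in 1:10) {
    a <- random_snapshot(n_nodes = 8, p = 0.3)
    b <- random_snapshot(n_nodes = 8, p = 0.3)
    for (mth in overlap_methods()) {
      expect_equal(step_overlap(a, b, mth), step_overlap(b, a, mth))
    }
  }
  other <- snapshot(nodes = as.character(1:9))
  expect_error(step_overlap(random_snapshot(8), other, "method1"),
               class = "temponet_error_validation")
})

test_that("per-pair overlaps respect the normaliser ordering and ranges", {
  set.seed(23)
  for (rep in 1:50) {
    a <- random_snapshot(n_nodes = 10, p = runif(1, 0.05, 0.5))
    b <- random_snapshot(n_nodes = 10, p = runif(1, 0.05, 0.5))
    c1 <- step_overlap(a, b, "method1")
    c2 <- step_overlap(a, b, "method2")
    c3 <- step_overlap(a, b, "method3")
    expect_gte(c1, 0); expect_lte(c1, 1)
    if (!is.na(c3)) {
      expect_gte(c3, 0); expect_lte(c3, 1)
      expect_lte(c1, c3 + 1e-12)
      expect_lte(c3, c2 + 1e-12)
    }
  }
})

test_that("temporal correlation reproduces the worked summary values of all three examples", {
  expected <- list(
    example1 = c(method1 = 0.70, method2 = 1.20, method3 = 0.70),
    example2 = c(method1 = 0.56, method2 = 1.20, method3 = 0.70),
    example3 = c(method1 = 0.47, method2 = 1.03, method3 = 0.66)
  )
  for (id in fixture_ids) {
    net <- build_fixture(id)
    for (mth in overlap_methods()) {
      expect_equal(round(temporal_correlation(net, mth), 2),
                   unname(expected[[id]][mth]),
                   label = paste(id, mth))
    }
  }
})

test_that("temporal correlation equals the direct mean of independently computed step overlaps", {
  set.seed(77)
  snaps <- replicate(5, random_snapshot(n_nodes = 8, p = 0.4), simplify = FALSE)
  net <- temporal_network(snaps)
  for (mth in overlap_methods()) {
    direct <- mean(vapply(1:4, function(k) {
      step_overlap(snaps[[k]], snaps[[k + 1]], mth)
    }, numeric(1)))
    expect_equal(temporal_correlation(net, mth), direct, tolerance = 1e-12)
  }
})

test_that("a series of identical edge-bearing snapshots has active-node correlation exactly 1", {
  s <- snapshot(data.frame(from = c("a", "c"), to = c("b", "d")),
                nodes = c("a", "b", "c", "d", "e"))
  net <- temporal_network(list(s, s, s, s))
  expect_equal(temporal_correlation(net, "method3"), 1)
  expect_lt(temporal_correlation(net, "method1"), 1)  # isolated node drags it down
})

test_that("undefined-pair policies skip, zero and error behave as documented", {
  s <- snapshot(data.frame(from = "a", to = "b"), nodes = c("a", "b"))
  empty <- snapshot(nodes = c("a", "b"))
  net <- temporal_network(list(s, s, empty, empty))
  # pairs: (s,s)=1, (s,empty)=0, (empty,empty)=0/0
  expect_message(v_skip <- temporal_correlation(net, "method3", undefined = "skip"),
                 "Skipping 1")
  expect_equal(v_skip, 0.5)
  expect_equal(temporal_correlation(net, "method3", undefined = "zero"), 1 / 3)
  expect_error(temporal_correlation(net, "method3", undefined = "error"),
               class = "temponet_error_undefined")
  all_empty <- temporal_network(list(empty, empty))
  expect_error(suppressMessages(
    temporal_correlation(all_empty, "method3", undefined = "skip")),
    class = "temponet_error_undefined")
  expect_error(temporal_correlation(temporal_network(list(s)), "method1"),
               class = "temponet_error_parameter")
})

test_that("overlap series rows are consistent with individual step calls", {
  set.seed(99)
  snaps <- replicate(4, random_snapshot(n_nodes = 7, p = 0.35), simplify = FALSE)
  net <- temporal_network(snaps)
  series <- overlap_series(net)
  expect_equal(nrow(series), 3)
  for (k in seq_len(3)) {
    for (mth in overlap_methods()) {
      expect_equal(series[[mth]][k],
                   step_overlap(snaps[[k]], snaps[[k + 1]], mth))
    }
    expect_equal(series$raw_sum[k], raw_sum_oracle(snaps[[k]], snaps[[k + 1]]),
                 tolerance = 1e-12)
  }
})

test_that("zero overlap occurs exactly when consecutive snapshots share no edge structure", {
  a <- snapshot(data.frame(from = "1", to = "2"), nodes = as.character(1:4))
  b <- snapshot(data.frame(from = "3", to = "4"), nodes = as.character(1:4))
  expect_equal(step_overlap(a, b, "method1"), 0)
  expect_equal(step_overlap(a, b, "method3"), 0)
})
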