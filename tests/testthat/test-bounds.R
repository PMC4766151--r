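test_that("per-pair ratio identity: value quotient equals normaliser quotient exactly", {
  net <- build_fixture("example1")
  r <- pairwise_ratios(net)
  # identical split-pair snapshots: max largest component 2 over N = 4
  expect_equal(r$r12[2], 2 / 4)      # value quotient: method1 = 1, method2 = 2
  expect_equal(r$r12_normaliser[2], 2 / 4)

  set.seed(207)
  checked <- 0
  while (checked < 200) {
    a <- random_snapshot(n_nodes = 8, p = runif(1, 0.1, 0.6))
    b <- random_snapshot(n_nodes = 8, p = runif(1, 0.1, 0.6))
    net <- temporal_network(list(a, b))
    r <- pairwise_ratios(net)
    if (!is.na(r$r12)) {
      expect_equal(r$r12, r$r12_normaliser, tolerance = 1e-12)
      checked <- checked + 1
    }
    if (!is.na(r$r13)) {
      expect_equal(r$r13, r$r13_normaliser, tolerance = 1e-12)
    }
  }
})

test_that("ratios with identical normalisers are exactly 1", {
  s <- snapshot(data.frame(from = c("1", "2"), to = c("2", "3")),
                nodes = as.character(1:3))
  net <- temporal_network(list(s, s))
  r <- pairwise_ratios(net)
  expect_equal(r$r12, 1)
  expect_equal(r$r13, 1)
})

test_that("averaged underestimation matches the looped normaliser mean", {
  # split-pair fixture: max largest-component sizes over the two pairs are 4 and 2
  expect_equal(averaged_underestimation(build_fixture("example2"), vs = "method2"),
               mean(c(4, 2)) / 5)
  # all nodes connected in every snapshot -> no underestimation
  full <- snapshot(data.frame(from = c("1", "2", "3"), to = c("2", "3", "1")),
                   nodes = as.character(1:3))
  net_full <- temporal_network(list(full, full, full))
  expect_equal(averaged_underestimation(net_full, vs = "method2"), 1)
  expect_equal(averaged_underestimation(net_full, vs = "method3"), 1)

  set.seed(59)
  snaps <- replicate(5, random_snapshot(n_nodes = 9, p = 0.3), simplify = FALSE)
  net <- temporal_network(snaps)
  looped2 <- mean(vapply(1:4, function(k) {
    max(bfs_component_sizes(snaps[[k]])[1], bfs_component_sizes(snaps[[k + 1]])[1]) / 9
  }, numeric(1)))
  expect_equal(averaged_underestimation(net, vs = "method2"), looped2,
               tolerance = 1e-12)
  for (vs in c("method2", "method3")) {
    au <- averaged_underestimation(net, vs = vs)
    expect_gt(au, 0); expect_lte(au, 1)
  }
})

test_that("distortion bounds collapse to 1 for identical fully-connected snapshots", {
  full <- snapshot(data.frame(from = c("1", "1", "2"), to = c("2", "3", "3")),
                   nodes = as.character(1:3))
  net <- temporal_network(list(full, full, full))
  rep_ <- correlation_bounds(net)
  expect_equal(rep_$min_c, 1)
  td <- tidy(rep_)
  expect_equal(td$lower, rep(1, 3))
  expect_equal(td$observed, rep(1, 3))
  expect_equal(td$upper, rep(1, 3))
  expect_true(all(td$within_bounds))
})

test_that("degenerate minC = 0 yields [0, Inf) bounds that still contain the observed quotient", {
  net <- build_fixture("example1")   # node 3 has disjoint neighbourhoods at the first step
  rep_ <- correlation_bounds(net)
  expect_equal(rep_$min_c, 0)
  td <- tidy(rep_)
  expect_equal(td$lower, rep(0, 3))
  expect_true(all(is.infinite(td$upper)))
  # observed C1/C2 from the worked values 0.70 / 1.20
  expect_equal(round(td$observed[td$comparison == "C1/C2"], 3), round(0.7 / 1.2, 3),
               tolerance = 0.01)
  expect_true(all(td$within_bounds))
})

test_that("bounds are never violated on random dense networks with positive minC", {
  set.seed(811)
  n_checked <- 0
  n_tried <- 0
  while (n_checked < 200 && n_tried < 2000) {
    n_tried <- n_tried + 1
    snaps <- replicate(3, random_snapshot(n_nodes = 7, p = 0.85), simplify = FALSE)
    net <- temporal_network(snaps)
    rep_ <- correlation_bounds(net)
    if (is.na(rep_$min_c) || rep_$min_c <= 0) next
    td <- tidy(rep_)
    ok <- !is.na(td$within_bounds)
    expect_true(all(td$within_bounds[ok]),
                info = paste("violation at attempt", n_tried))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 200)
})

test_that("active-only minC option gives a finite, still-valid interval on sparse fixtures", {
  net <- build_fixture("example3")
  lit <- correlation_bounds(net, min_over = "all")
  act <- correlation_bounds(net, min_over = "active")
  expect_equal(lit$min_c, 0)
  expect_gte(act$min_c, lit$min_c)
  td <- tidy(act)
  expect_true(all(td$within_bounds | is.na(td$within_bounds)))
})

test_that("glance flags zero-denominator quotients as undefined", {
  a <- snapshot(data.frame(from = "1", to = "2"), nodes = as.character(1:4))
  b <- snapshot(data.frame(from = "3", to = "4"), nodes = as.character(1:4))
  net <- temporal_network(list(a, b))   # C = 0 under every method
  td <- tidy(correlation_bounds(net))
  expect_true(all(is.na(td$observed)))
  g <- glance(correlation_bounds(net))
  expect_equal(g$c_method1, 0)
})
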