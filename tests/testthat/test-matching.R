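gallery <- fixture_gallery()

test_that("the bipartite transform preserves node and link counts", {
  bip <- to_bipartite(gallery$fig_model)
  expect_equal(bip$n, 7L)
  expect_length(bip$eplus, 7L)
  bip2 <- to_bipartite(gallery$path3)
  expect_equal(bip2$nodes[bip2$eplus], c("a", "b"))
  expect_equal(bip2$nodes[bip2$eminus], c("b", "c"))
  empty <- edge_network(character(0), character(0), nodes = c("a", "b"))
  expect_length(to_bipartite(empty)$eplus, 0L)
})

test_that("matching sizes match exhaustive enumeration on the named fixtures", {
  for (name in c("path3", "cycle3", "star4", "fig_model", "five_node")) {
    net <- gallery[[name]]
    expect_equal(maximum_matching(net)$size,
                 length(enumerate_maximum_matchings(net)[[1]]),
                 info = name)
  }
})

test_that("matching size is independent of edge order; the matched set need not be", {
  net <- gallery$star4
  sizes <- vapply(1:10, function(s) maximum_matching(net, seed = s)$size,
                  numeric(1))
  expect_true(all(sizes == 1L))
  matched <- vapply(1:10, function(s)
    maximum_matching(net, seed = s)$matched_links$to, character(1))
  expect_gt(length(unique(matched)), 1L)  # the sampling handle works
})

test_that("matching size agrees with an independent matcher and brute force on random graphs", {
  set.seed(42)
  for (k in 1:25) {
    net <- random_small_network(n = sample(3:7, 1), p = 0.3)
    m <- maximum_matching(net)
    expect_equal(m$size, length(enumerate_maximum_matchings(net)[[1]]))
    # independent route: igraph's bipartite matcher on the split graph
    bip <- to_bipartite(net)
    g <- igraph::make_bipartite_graph(
      rep(c(FALSE, TRUE), each = bip$n),
      rbind(bip$eplus, bip$n + bip$eminus))
    expect_equal(m$size, igraph::max_bipartite_match(g)$matching_size)
  }
})

test_that("drivers are the unmatched nodes; perfect matchings still need one input", {
  m <- maximum_matching(gallery$path3)
  expect_equal(mdms_from_matching(gallery$path3, m), "a")
  # 3-cycle: perfect matching, driver set collapses to one canonical node
  mc <- maximum_matching(gallery$cycle3)
  expect_equal(mc$size, 3L)
  expect_equal(mdms_from_matching(gallery$cycle3, mc), "a")
  # star: every MDMS has size 3 = max(N - |M|, 1) and contains the hub
  ms <- maximum_matching(gallery$star4)
  d <- mdms_from_matching(gallery$star4, ms)
  expect_length(d, 3L)
  expect_true("h" %in% d)
})

test_that("a non-maximum matching is rejected", {
  net <- gallery$path3
  m <- maximum_matching(net)
  m$match_plus <- integer(3); m$match_minus <- integer(3); m$size <- 0L
  expect_error(mdms_from_matching(net, m), "not maximum")
})

test_that("MDMS sampling finds exactly the enumerable driver sets", {
  s <- suppressWarnings(sample_mdms(gallery$star4, 10, seed = 1))
  expect_setequal(vapply(s, paste, character(1), collapse = ","),
                  c("h,l1,l2", "h,l1,l3", "h,l2,l3"))
  expect_warning(sample_mdms(gallery$path3, 2, seed = 1), "only 1 distinct")
  p <- suppressWarnings(sample_mdms(gallery$path3, 2, seed = 1))
  expect_equal(p[[1]], "a")
})

test_that("sampling is reproducible and MDMS sizes obey max(N - |M|, 1)", {
  net <- gallery$five_node
  s1 <- sample_mdms(net, 2, seed = 7)
  s2 <- sample_mdms(net, 2, seed = 7)
  expect_identical(s1, s2)
  msize <- attr(s1, "matching_size")
  expect_true(all(lengths(s1) == max(n_nodes(net) - msize, 1L)))
})

test_that("driver frequencies and classes follow the exact thresholds", {
  s <- suppressWarnings(sample_mdms(gallery$star4, 3, seed = 2))
  f <- driver_frequency(s)
  expect_equal(f$f_d[f$node == "h"], 1)
  expect_equal(f$class[f$node == "h"], "critical")
  expect_equal(f$f_d[f$node == "l1"], 2 / 3)
  expect_equal(f$class[f$node == "l1"], "high_frequency")
  # exact enumeration frequencies are reproduced
  oracle <- oracle_driver_frequency(gallery$star4)
  expect_equal(stats::setNames(f$f_d[match(names(oracle), f$node)],
                               names(oracle)), oracle)
})

test_that("absent nodes and the 0.6 boundary classify with an inclusive lower bound", {
  f <- driver_frequency(list(c("a"), c("a", "b")), nodes = c("a", "b", "z"))
  expect_equal(f$f_d[f$node == "z"], 0)
  expect_equal(f$class[f$node == "z"], "low_frequency")
  # exactly 0.6: 3 of 5 samples -> high_frequency (inclusive lower bound)
  f2 <- driver_frequency(list(c("a", "x1"), c("a", "x2"), c("a", "x3"),
                              c("b", "x4"), c("b", "x5")))
  expect_equal(f2$f_d[f2$node == "a"], 0.6)
  expect_equal(f2$class[f2$node == "a"], "high_frequency")
  expect_error(driver_frequency(list()), "empty")
})
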