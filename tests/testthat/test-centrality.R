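test_that("path centralities match hand evaluation", {
  cp <- compute_centralities(fixture_gallery()$path3)
  expect_equal(cp$B[cp$node == "b"], 1)   # the single a->c path passes b
  expect_equal(cp$C_out[cp$node == "a"], 1.5)  # 1/1 + 1/2
  expect_equal(cp$C_in[cp$node == "a"], 0)
  expect_equal(cp$C[cp$node == "a"], 1.5)      # undirected projection
  expect_equal(cp$D, cp$InD + cp$OutD)
})

test_that("a single node has all centralities zero", {
  cp <- compute_centralities(edge_network(character(0), character(0),
                                          nodes = "solo"))
  expect_equal(unlist(cp[1, c("D", "InD", "OutD", "B", "C_out", "C_in", "C")]),
               c(D = 0, InD = 0, OutD = 0, B = 0, C_out = 0, C_in = 0, C = 0))
})

test_that("betweenness equals the path-enumeration oracle on random graphs", {
  set.seed(61)
  for (k in 1:8) {
    net <- random_small_network(n = sample(4:7, 1), p = 0.35)
    cp <- compute_centralities(net)
    expect_equal(stats::setNames(cp$B, cp$node), oracle_betweenness(net))
  }
})

test_that("adding a link never lowers any out-closeness", {
  set.seed(71)
  for (k in 1:5) {
    net <- random_small_network(n = 6, p = 0.25)
    before <- compute_centralities(net)$C_out
    pool <- expand.grid(f = net$nodes, t = net$nodes,
                        stringsAsFactors = FALSE)
    pool <- pool[pool$f != pool$t, ]
    pool <- pool[!paste(pool$f, pool$t) %in%
                   paste(net$links$from, net$links$to), ]
    if (nrow(pool) == 0) next
    pick <- pool[sample.int(nrow(pool), 1), ]
    net2 <- edge_network(c(net$links$from, pick$f),
                         c(net$links$to, pick$t), nodes = net$nodes)
    after <- compute_centralities(net2)$C_out
    expect_true(all(after >= before - 1e-12))
  }
})

test_that("classical closeness switch gives reciprocal mean distances", {
  cp <- compute_centralities(fixture_gallery()$path3,
                             closeness = "classical")
  # igraph classical closeness from a: 1/(d(a,b)+d(a,c)) = 1/3
  expect_equal(cp$C_out[cp$node == "a"], 1 / 3)
})

test_that("tertile splits are balanced, deterministic, and keep ties together", {
  s <- stats::setNames(c(1, 2, 3, 4, 5, 6), letters[1:6])
  fam <- tertile_split(s)
  expect_equal(lengths(fam[c("low", "medium", "high")]),
               c(low = 2L, medium = 2L, high = 2L))
  expect_equal(fam$low, c("a", "b"))
  # a tie group straddling a cut stays in the lower bin
  s2 <- stats::setNames(c(1, 2, 2, 2, 5, 6, 7), letters[1:7])
  fam2 <- tertile_split(s2)
  expect_true(all(c("b", "c", "d") %in% fam2$low))
  expect_error(tertile_split(c(a = 1, b = 2)), "at least 3")
  expect_warning(tertile_split(stats::setNames(rep(1, 5), letters[1:5])),
                 "ties collapse")
})

test_that("fraction profiles sum to one and detect concentration", {
  s <- stats::setNames(1:9, letters[1:9])
  fam <- tertile_split(s)
  pr <- fraction_profile(c("a", "b", "c"), list(score = fam))
  expect_equal(pr$frac_low + pr$frac_medium + pr$frac_high, 1)
  expect_equal(c(pr$frac_low, pr$frac_medium, pr$frac_high), c(1, 0, 0))
  pr_all <- fraction_profile(letters[1:9], list(score = fam))
  expect_equal(c(pr_all$frac_low, pr_all$frac_medium, pr_all$frac_high),
               c(1, 1, 1) / 3)
  expect_error(fraction_profile(character(0), list(score = fam)), "empty")
})
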