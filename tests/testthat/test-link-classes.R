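gallery <- fixture_gallery()

test_that("link classes match the documented small cases", {
  single <- classify_links(edge_network("a", "b"))
  expect_equal(single$link_class, "critical")
  fork <- classify_links(edge_network(c("a", "c"), c("b", "b")))
  expect_equal(fork$link_class, c("ordinary", "ordinary"))
  cyc <- classify_links(gallery$cycle3)
  expect_true(all(cyc$link_class == "critical"))
  counts <- attr(cyc, "counts")
  expect_equal(sum(counts), n_links(gallery$cycle3))
})

test_that("classes agree with enumeration over all maximum matchings", {
  for (name in c("path3", "cycle3", "star4", "fig_model", "five_node")) {
    net <- gallery[[name]]
    got <- classify_links(net)
    got <- got[!net$links$self_loop, ]
    oracle <- oracle_link_classes(net)
    expect_equal(stats::setNames(got$link_class,
                                 paste(got$from, "->", got$to)),
                 oracle[paste(got$from, "->", got$to)], info = name)
  }
  set.seed(99)
  for (k in 1:20) {
    net <- random_small_network(n = sample(4:7, 1), p = 0.35)
    got <- classify_links(net)
    oracle <- oracle_link_classes(net)
    expect_equal(stats::setNames(got$link_class,
                                 paste(got$from, "->", got$to)),
                 oracle[paste(got$from, "->", got$to)])
  }
})

test_that("the classification does not depend on which maximum matching is used", {
  set.seed(4)
  for (k in 1:6) {
    net <- random_small_network(n = 8, p = 0.25)
    base <- classify_links(net)$link_class
    for (s in 1:5)
      expect_equal(classify_links(net, seed = s)$link_class, base)
  }
})

test_that("removing links has the class-specific effect on the matching", {
  set.seed(17)
  for (k in 1:6) {
    net <- random_small_network(n = 7, p = 0.3)
    cls <- classify_links(net)
    m0 <- maximum_matching(net)$size
    for (i in seq_len(nrow(cls))) {
      sub <- net$links[-i, , drop = FALSE]
      net2 <- edge_network(sub$from, sub$to, nodes = net$nodes)
      m1 <- maximum_matching(net2)$size
      if (cls$link_class[i] == "critical") expect_equal(m1, m0 - 1L)
      else expect_equal(m1, m0)
    }
  }
})

test_that("self-loops are their own alternating cycles, hence ordinary", {
  net <- build_network(parse_reactions(c("R1: a[c] -> a[c] + b[c]")))
  cls <- classify_links(net)
  expect_equal(cls$link_class[cls$from == "a[c]" & cls$to == "a[c]"],
               "ordinary")
  expect_equal(cls$link_class[cls$to == "b[c]"], "critical")
})

test_that("enrichment reports per-set fractions and exports chi-square counts", {
  rx <- parse_reactions(c(
    "R1: u1[e] -> a[c] ; class=non_core",
    "R2: a[c] -> b[c] ; class=core_high",
    "R3: b[c] -> c[c] ; class=core_high",
    "R4: d[c] -> c[c] ; class=core_moderate"))
  net <- build_network(rx)
  enr <- link_class_enrichment(classify_links(net), link_annotation_table(net))
  ens <- enr$summary[enr$summary$set == "Ensemble", ]
  expect_equal(ens$n_links, 4L)
  expect_equal(ens$frac_core_high, 0.5)
  expect_equal(ens$frac_transport, 0.25)
  expect_equal(ens$frac_env_to_cell, 0.25)
  expect_equal(unname(rowSums(enr$counts_multi)[["Ensemble"]]), 4L)
  # a set with no links reports undefined fractions, not zero
  red <- enr$summary[enr$summary$set == "redundant", ]
  if (red$n_links == 0L) expect_true(is.na(red$frac_core_high))
})

test_that("uniform annotations give fraction one in every non-empty set", {
  rx <- parse_reactions(c(
    "R1: a[c] -> b[c] ; class=non_core",
    "R2: b[c] -> c[c] ; class=non_core"))
  net <- build_network(rx)
  enr <- link_class_enrichment(classify_links(net), link_annotation_table(net))
  sm <- enr$summary
  expect_true(all(sm$frac_non_core[sm$n_links > 0] == 1))
})

test_that("missing annotations are an error", {
  net <- edge_network(c("a", "b"), c("b", "c"))
  ann <- data.frame(from = "a", to = "b", reaction_class = "non_core",
                    n_classes = 1L, is_transport = FALSE,
                    crosses_into_cell = FALSE)
  expect_error(link_class_enrichment(classify_links(net), ann),
               "annotation missing")
})
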