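test_that("the substrate-to-product rule yields the documented 7-node, 7-link network", {
  net <- fixture_gallery()$fig_model
  expect_equal(n_nodes(net), 7L)
  expect_equal(n_links(net), 7L)
  got <- paste(net$links$from, net$links$to, sep = ">")
  want <- c("hgentis[c]>4mlacac[c]", "hgentis[c]>h[c]", "o2[c]>4mlacac[c]",
            "o2[c]>h[c]", "h[c]>h[m]", "h[m]>h2co3[m]", "hco3[m]>h2co3[m]")
  expect_setequal(got, want)
})

test_that("duplicate directed pairs collapse to one link with the union of reactions", {
  rx <- parse_reactions(c("R1: a[c] -> b[c]", "R2: a[c] -> b[c]"))
  net <- build_network(rx)
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_links(net), 1L)
  expect_setequal(net$link_reactions[[1]], c("R1", "R2"))
})

test_that("reversible reactions expand to both directions, controllably", {
  rx <- parse_reactions("R1: a[c] <-> b[c]")
  net <- build_network(rx)
  expect_equal(n_links(net), 2L)
  expect_setequal(paste(net$links$from, net$links$to),
                  c("a[c] b[c]", "b[c] a[c]"))
  net1 <- build_network(rx, expand_reversible = FALSE)
  expect_equal(n_links(net1), 1L)
})

test_that("self-loops are retained and flagged", {
  net <- build_network(parse_reactions("R1: a[c] + b[c] -> a[c]"))
  expect_true(any(net$links$self_loop))
  expect_equal(net$links$from[net$links$self_loop], "a[c]")
})

test_that("every metabolite of every reaction is a node, and the link bound holds", {
  set.seed(7)
  for (k in 1:5) {
    rx <- generate_reactions(synthetic_model_spec(
      n_metabolites = 30L, n_reactions = 25L, seed = k,
      reversible_fraction = 0))
    net <- build_network(rx)
    mets <- unique(unlist(lapply(rx, function(r) c(r$substrates, r$products))))
    expect_setequal(net$nodes, mets)
    bound <- sum(vapply(rx, function(r)
      length(r$substrates) * length(r$products), numeric(1)))
    expect_lte(n_links(net), bound)
  }
})

test_that("edge-list export and import round-trip", {
  net <- fixture_gallery()$five_node
  path <- withr::local_tempfile(fileext = ".edgelist")
  write_edgelist(net, path)
  net2 <- read_edgelist(path)
  expect_equal(net2$nodes, net$nodes)
  expect_equal(net2$links, net$links)
})

test_that("transposition reverses every link and is an involution", {
  net <- fixture_gallery()$five_node
  tr <- transpose_network(net)
  expect_setequal(paste(tr$links$from, tr$links$to),
                  paste(net$links$to, net$links$from))
  back <- transpose_network(tr)
  expect_equal(back$links, net$links)
})

test_that("link annotations carry class, transport and boundary-crossing status", {
  rx <- parse_reactions(c(
    "R1: glc[e] -> glc[c] ; class=non_core",
    "R2: glc[c] -> pyr[c] ; class=core_high",
    "R3: glc[c] -> pyr[c] ; class=non_core"))
  net <- build_network(rx)
  ann <- link_annotation_table(net)
  tr_link <- ann[ann$from == "glc[e]", ]
  expect_true(tr_link$is_transport)
  expect_true(tr_link$crosses_into_cell)
  mixed <- ann[ann$from == "glc[c]" & ann$to == "pyr[c]", ]
  expect_equal(mixed$reaction_class, "core_high;non_core")
  expect_equal(mixed$n_classes, 2L)
  expect_false(mixed$is_transport)
  expect_false(mixed$crosses_into_cell)
})

test_that("annotation of a reaction-free network is an error", {
  net <- edge_network("a", "b")
  expect_error(link_annotation_table(net), "inducing-reaction")
})
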