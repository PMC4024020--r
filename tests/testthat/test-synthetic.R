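test_that("boundary metabolites are substrate-only and become critical drivers", {
  spec <- synthetic_model_spec(n_metabolites = 100L, n_reactions = 135L,
                               boundary_fraction = 0.1, seed = 3)
  rx <- generate_reactions(spec)
  net <- build_network(rx)
  indeg <- netctrl:::in_degree(net)
  boundary <- grep("^m0(0[1-9]|10)\\[", net$nodes, value = TRUE)
  expect_length(boundary, 10L)
  expect_true(all(indeg[boundary] == 0L))
  expect_gte(sum(indeg == 0L), 10L)
  cc <- exact_node_control_class(net)
  expect_true(all(cc$class[cc$node %in% boundary] == "critical"))
})

test_that("transport fraction zero keeps every link within one compartment", {
  spec <- synthetic_model_spec(n_metabolites = 40L, n_reactions = 30L,
                               transport_fraction = 0,
                               boundary_fraction = 0, seed = 5)
  net <- build_network(generate_reactions(spec))
  expect_true(all(met_compartment(net$links$from) ==
                    met_compartment(net$links$to)))
})

test_that("generation is a pure function of the spec and round-trips through text", {
  spec <- synthetic_model_spec(n_metabolites = 50L, n_reactions = 60L,
                               seed = 11)
  r1 <- generate_reactions(spec)
  r2 <- generate_reactions(spec)
  expect_identical(format_reactions(r1), format_reactions(r2))
  reparsed <- parse_reactions(format_reactions(r1))
  n1 <- build_network(r1); n2 <- build_network(reparsed)
  expect_equal(n2$nodes, n1$nodes)
  expect_equal(n2$links, n1$links)
})

test_that("class mix proportions are respected on average", {
  spec <- synthetic_model_spec(n_metabolites = 80L, n_reactions = 400L,
                               seed = 2)
  rx <- generate_reactions(spec)
  cls <- table(vapply(rx, `[[`, character(1), "reaction_class"))
  expect_gt(cls[["core_high"]] / 400, 0.5)
  expect_lt(cls[["core_moderate"]] / 400, 0.25)
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_model_spec(compartments = "c",
                                    extracellular = "c",
                                    transport_fraction = 0.5),
               "two compartments")
  expect_error(generate_reactions(synthetic_model_spec(
    n_metabolites = 100L, n_reactions = 5L, boundary_fraction = 0.5)),
    "boundary metabolites")
})

test_that("planted networks honour their probabilities and seed", {
  spec <- planted_partition_spec(n_modules = 3, nodes_per_module = 6,
                                 p_within = 1, p_between = 0, seed = 9)
  pl <- generate_planted_network(spec)
  comps <- igraph::components(as_igraph(pl$network, directed = FALSE))
  expect_equal(comps$no, 3L)
  # disconnected planted modules are recovered exactly
  part <- simulated_annealing(pl$network, sa_config(seed = 1))
  expect_equal(nmi(part$membership, pl$membership), 1)
  pl2 <- generate_planted_network(spec)
  expect_identical(pl2$network$links, pl$network$links)
})

test_that("equal within and between probabilities give near-zero planted modularity", {
  spec <- planted_partition_spec(n_modules = 4, nodes_per_module = 8,
                                 p_within = 0.3, p_between = 0.3, seed = 13)
  pl <- generate_planted_network(spec)
  expect_lt(abs(modularity_score(pl$network, pl$membership)), 0.1)
})

test_that("the fixture gallery exposes the documented ground truths", {
  g <- fixture_gallery()
  expect_named(g, c("path3", "cycle3", "star4", "two_cliques",
                    "fig_model", "five_node"))
  expect_equal(n_nodes(g$fig_model), 7L)
  expect_equal(n_links(g$fig_model), 7L)
  expect_equal(n_nodes(g$two_cliques), 20L)
  expect_equal(n_links(g$two_cliques), 90L)
})
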