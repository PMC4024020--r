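#' Specification for a synthetic compartmentalized reaction set
#'
#' Describes a random reaction model with the structural features the
#' controllability pipeline relies on: compartmentalized metabolites with
#' a designated extracellular compartment, boundary metabolites that only
#' ever appear as substrates (so their network in-degree is zero),
#' transport reactions crossing compartments, and a three-way
#' reaction-class mix. The default class mix (60/15/25 percent core-high /
#' core-moderate / non-core) and transport fraction (about a fifth of
#' reactions) mirror the whole-network composition reported for
#' genome-scale liver models; the default model size keeps the
#' reaction-to-metabolite ratio near 1.34.
#'
#' @param n_metabolites,n_reactions Model size.
#' @param compartments Compartment codes; `extracellular` must be one of
#'   them.
#' @param extracellular Code of the extracellular space.
#' @param transport_fraction Fraction of reactions crossing compartments.
#' @param boundary_fraction Fraction of metabolites designated boundary
#'   (extracellular, substrate-only).
#' @param class_mix Named proportions for `core_high`, `core_moderate`,
#'   `non_core`; must sum to 1.
#' @param reversible_fraction Fraction of reversible reactions (reactions
#'   touching boundary metabolites stay irreversible so boundary in-degree
#'   remains zero).
#' @param max_side Largest substrate/product count; counts are drawn from
#'   a geometric distribution truncated to `1..max_side`.
#' @param geom_p Success probability of that geometric distribution.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return List of class `"synthetic_model_spec"`.
#' @export
synthetic_model_spec <- function(n_metabolites = 100L, n_reactions = 135L,
                                 compartments = c("c", "m", "e"),
                                 extracellular = "e",
                                 transport_fraction = 0.2,
                                 boundary_fraction = 0.1,
                                 class_mix = c(core_high = 0.60,
                                               core_moderate = 0.15,
                                               non_core = 0.25),
                                 reversible_fraction = 0.1,
                                 max_side = 4L, geom_p = 0.5, seed = 1L) {
  stopifnot(n_metabolites >= 2, n_reactions >= 1,
            extracellular %in% compartments,
            transport_fraction >= 0, transport_fraction <= 1,
            boundary_fraction >= 0, boundary_fraction < 1,
            abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in%
                  c("core_high", "core_moderate", "non_core")),
            reversible_fraction >= 0, reversible_fraction <= 1,
            max_side >= 1, geom_p > 0, geom_p <= 1)
  if (transport_fraction > 0 && length(compartments) < 2L)
    stop("transport reactions need at least two compartments")
  structure(as.list(environment()), class = "synthetic_model_spec")
}

rgeom_trunc <- function(n, p, max_k) {
  1L + (stats::rgeom(n, p) %% max_k)
}

#' Generate a synthetic reaction set
#'
#' Draws a reaction set honouring a [synthetic_model_spec()]: each boundary
#' metabolite is used as a substrate of at least one transport (uptake)
#' reaction and never as a product, transport reactions connect distinct
#' compartments, non-transport reactions stay within one compartment, and
#' classes are sampled from the configured mix. Identical spec (including
#' seed) gives byte-identical output.
#'
#' @param spec A `"synthetic_model_spec"`.
#' @return A `reaction_set`, as from [parse_reactions()].
#' @export
generate_reactions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_model_spec"))
  with_seed(spec$seed, {
    n <- spec$n_metabolites
    nb <- round(spec$boundary_fraction * n)
    if (nb > spec$n_reactions)
      stop("more boundary metabolites than reactions: cannot give each an uptake reaction")
    comp <- sample(spec$compartments, n, replace = TRUE)
    comp[seq_len(nb)] <- spec$extracellular          # boundary first
    ids <- sprintf("m%03d[%s]", seq_len(n), comp)
    boundary <- ids[seq_len(nb)]
    internal <- setdiff(ids, boundary)               # may be products
    int_comp <- met_compartment(internal)
    by_comp <- split(internal, int_comp)
    usable <- names(by_comp)[lengths(by_comp) >= 2L]
    if (length(usable) == 0L)
      stop("infeasible spec: no compartment has two internal metabolites")

    classes <- sample(names(spec$class_mix), spec$n_reactions,
                      replace = TRUE, prob = spec$class_mix)
    reactions <- vector("list", spec$n_reactions)
    for (r in seq_len(spec$n_reactions)) {
      ns <- rgeom_trunc(1L, spec$geom_p, spec$max_side)
      np <- rgeom_trunc(1L, spec$geom_p, spec$max_side)
      uptake <- r <= nb
      transport <- uptake || stats::runif(1) < spec$transport_fraction
      if (transport && length(spec$compartments) >= 2L) {
        if (uptake) {
          subs <- boundary[r]
          if (ns > 1L)
            subs <- c(subs, sample(by_comp[[spec$extracellular]] %||%
                                     character(0),
                                   min(ns - 1L,
                                       length(by_comp[[spec$extracellular]]))))
          from_comp <- spec$extracellular
        } else {
          from_comp <- sample(usable, 1L)
          pool <- by_comp[[from_comp]]
          subs <- sample(pool, min(ns, length(pool)))
        }
        to_choices <- setdiff(names(by_comp), from_comp)
        to_choices <- to_choices[lengths(by_comp[to_choices]) >= 1L]
        if (length(to_choices) == 0L) to_choices <- usable
        to_comp <- if (length(to_choices) == 1L) to_choices
                   else sample(to_choices, 1L)
        pool <- setdiff(by_comp[[to_comp]], subs)
        if (length(pool) == 0L) pool <- setdiff(internal, subs)
        prods <- sample(pool, min(np, length(pool)))
      } else {
        cc <- if (length(usable) == 1L) usable else sample(usable, 1L)
        pool <- by_comp[[cc]]
        subs <- sample(pool, min(ns, max(1L, length(pool) - 1L)))
        pool2 <- setdiff(pool, subs)
        prods <- sample(pool2, min(np, length(pool2)))
      }
      touches_boundary <- any(c(subs, prods) %in% boundary)
      rev <- !touches_boundary && stats::runif(1) < spec$reversible_fraction
      reactions[[r]] <- make_reaction(sprintf("R%04d", r),
                                      sort(subs), sort(prods), rev,
                                      classes[r])
    }
    structure(reactions, class = "reaction_set")
  })
}

#' Specification for a planted-partition directed network
#'
#' @param n_modules Number of planted modules.
#' @param nodes_per_module Nodes in each module.
#' @param p_within,p_between Directed link probabilities inside and
#'   between modules; recovery experiments need `p_within > p_between`.
#' @param seed Integer seed.
#' @return List of class `"planted_partition_spec"`.
#' @export
planted_partition_spec <- function(n_modules = 4L, nodes_per_module = 10L,
                                   p_within = 0.6, p_between = 0.05,
                                   seed = 1L) {
  stopifnot(n_modules >= 1, nodes_per_module >= 1,
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1)
  structure(list(n_modules = n_modules,
                 nodes_per_module = nodes_per_module,
                 p_within = p_within, p_between = p_between, seed = seed),
            class = "planted_partition_spec")
}

#' Generate a planted-partition directed network
#'
#' Every ordered pair of distinct nodes receives a link independently with
#' probability `p_within` (same planted module) or `p_between`.
#'
#' @param spec A `"planted_partition_spec"`.
#' @return List with `network` (a `metabolite_network`) and `membership`
#'   (named integer vector of planted labels; isolated nodes are kept in
#'   the network's node set).
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "planted_partition_spec"))
  with_seed(spec$seed, {
    n <- spec$n_modules * spec$nodes_per_module
    ids <- sprintf("n%03d", seq_len(n))
    mem <- rep(seq_len(spec$n_modules), each = spec$nodes_per_module)
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    pairs <- pairs[pairs$i != pairs$j, ]
    p <- ifelse(mem[pairs$i] == mem[pairs$j], spec$p_within, spec$p_between)
    keep <- stats::runif(nrow(pairs)) < p
    net <- edge_network(ids[pairs$i[keep]], ids[pairs$j[keep]], nodes = ids)
    list(network = net, membership = stats::setNames(mem, ids))
  })
}

#' Gallery of small named fixture networks
#'
#' Deterministic toy networks used throughout the documentation and test
#' suite: `path3` (a -> b -> c), `cycle3`, `star4` (hub h feeding three
#' leaves), `two_cliques` (two disjoint 10-cliques, the canonical
#' two-module graph with modularity 0.5), `fig_model` (the network built
#' from a three-reaction worked example: an oxidation, a transport step
#' and an intracellular reaction; 7 nodes, 7 links), and `five_node` (a
#' small network with several distinct minimum driver sets).
#'
#' @return Named list of `metabolite_network` objects.
#' @export
fixture_gallery <- function() {
  fig_rx <- parse_reactions(c(
    "R1: hgentis[c] + o2[c] -> 4mlacac[c] + h[c]",
    "R2: h[c] -> h[m]",
    "R3: h[m] + hco3[m] -> h2co3[m]"))
  list(
    path3 = edge_network(c("a", "b"), c("b", "c")),
    cycle3 = edge_network(c("a", "b", "c"), c("b", "c", "a")),
    star4 = edge_network(c("h", "h", "h"), c("l1", "l2", "l3")),
    two_cliques = local({
      cl <- function(prefix) {
        v <- sprintf("%s%02d", prefix, 1:10)
        p <- t(utils::combn(v, 2))
        data.frame(from = p[, 1], to = p[, 2], stringsAsFactors = FALSE)
      }
      e <- rbind(cl("a"), cl("b"))
      edge_network(e$from, e$to)
    }),
    fig_model = build_network(fig_rx),
    five_node = edge_network(c("x1", "x1", "x2", "x3", "x4"),
                             c("x2", "x3", "x4", "x4", "x5"))
  )
}
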