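#' Build the directed metabolite network from a reaction set
#'
#' Applies the substrate-to-product rule: for every reaction, a directed
#' link runs from each substrate to each product; a reversible reaction
#' additionally contributes the product-to-substrate links. A directed pair
#' induced by several reactions appears as a single link that remembers the
#' union of its inducing reaction ids. Self-loops (a metabolite that is both
#' substrate and product of one reaction) are retained and flagged; they are
#' excluded from matching computations downstream by default.
#'
#' @param reactions A `reaction_set` from [parse_reactions()].
#' @param expand_reversible Add the reversed links of reversible reactions
#'   (default `TRUE`).
#' @return A `metabolite_network`: list with `nodes` (character vector,
#'   canonical sort order), `links` (data frame with columns `from`, `to`,
#'   `self_loop`) and `link_reactions` (list parallel to `links` rows with
#'   the inducing reaction ids; empty for networks imported from edge
#'   lists).
#' @examples
#' net <- build_network(parse_reactions("R1: a[c] -> b[c] + c[c]"))
#' n_links(net)
#' @export
build_network <- function(reactions, expand_reversible = TRUE) {
  stopifnot(inherits(reactions, "reaction_set") || is.list(reactions))
  from <- character(); to <- character(); rid <- character()
  for (r in reactions) {
    pairs <- expand.grid(s = r$substrates, p = r$products,
                         stringsAsFactors = FALSE)
    from <- c(from, pairs$s); to <- c(to, pairs$p)
    rid <- c(rid, rep(r$id, nrow(pairs)))
    if (expand_reversible && r$reversible) {
      from <- c(from, pairs$p); to <- c(to, pairs$s)
      rid <- c(rid, rep(r$id, nrow(pairs)))
    }
  }
  nodes <- sort(unique(unlist(lapply(reactions, function(r)
    c(r$substrates, r$products)))))
  key <- link_key(from, to)
  keep <- !duplicated(key)
  lr <- lapply(split(rid, key), unique)
  links <- data.frame(from = from[keep], to = to[keep],
                      stringsAsFactors = FALSE)
  o <- order(links$from, links$to)
  links <- links[o, , drop = FALSE]
  rownames(links) <- NULL
  links$self_loop <- links$from == links$to
  new_metabolite_network(nodes, links,
                         link_reactions = lr[link_key(links$from, links$to)],
                         reactions = reactions)
}

new_metabolite_network <- function(nodes, links, link_reactions = NULL,
                                   reactions = NULL) {
  structure(list(nodes = nodes, links = links,
                 link_reactions = link_reactions,
                 reactions = reactions),
            class = "metabolite_network")
}

#' Construct a network directly from directed links
#'
#' @param from,to Character vectors of source and target node ids.
#' @param nodes Optional node universe (isolated nodes allowed); defaults
#'   to the ids appearing in the links.
#' @return A `metabolite_network` without reaction annotations.
#' @export
edge_network <- function(from, to, nodes = NULL) {
  stopifnot(length(from) == length(to))
  key <- link_key(from, to)
  keep <- !duplicated(key)
  links <- data.frame(from = as.character(from[keep]),
                      to = as.character(to[keep]),
                      stringsAsFactors = FALSE)
  o <- order(links$from, links$to)
  links <- links[o, , drop = FALSE]
  rownames(links) <- NULL
  links$self_loop <- links$from == links$to
  nodes <- sort(unique(c(nodes, links$from, links$to)))
  new_metabolite_network(nodes, links)
}

#' @rdname edge_network
#' @param path Two-column whitespace-separated edge-list file.
#' @export
read_edgelist <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("from", "to"))
  edge_network(tab$from, tab$to)
}

#' @rdname edge_network
#' @param network A `metabolite_network` to export.
#' @export
write_edgelist <- function(network, path) {
  utils::write.table(network$links[, c("from", "to")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' Network size accessors and transpose
#'
#' @param network A `metabolite_network`.
#' @return Integer count, or the transposed network (every link reversed).
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_links <- function(network) nrow(network$links)

#' @rdname n_nodes
#' @export
transpose_network <- function(network) {
  net <- network
  net$links <- data.frame(from = network$links$to, to = network$links$from,
                          self_loop = network$links$self_loop,
                          stringsAsFactors = FALSE)
  o <- order(net$links$from, net$links$to)
  net$links <- net$links[o, , drop = FALSE]
  rownames(net$links) <- NULL
  net$link_reactions <- network$link_reactions[o]
  net
}

#' Convert to an igraph object
#'
#' @param network A `metabolite_network`.
#' @param directed Keep link directions (default) or project to the
#'   undirected simple graph used by the modularity machinery.
#' @return An igraph graph whose vertex names are the node ids.
#' @export
as_igraph <- function(network, directed = TRUE) {
  g <- igraph::graph_from_data_frame(network$links[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = network$nodes)
  if (!directed)
    g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"),
                          remove.loops = TRUE)
  g
}

in_degree <- function(network) {
  tab <- table(factor(network$links$to, levels = network$nodes))
  stats::setNames(as.integer(tab), network$nodes)
}

#' @export
print.metabolite_network <- function(x, ...) {
  cat("Metabolite network:", n_nodes(x), "nodes,", n_links(x), "links")
  if (any(x$links$self_loop)) cat(" (", sum(x$links$self_loop), "self-loops )")
  cat("\n")
  invisible(x)
}

#' Per-link reaction annotations
#'
#' Labels every link of a reaction-built network with the classes and
#' transport status of its inducing reactions. A link is a transport link
#' if any inducing reaction crosses compartments, and crosses into the cell
#' if some inducing reaction has a substrate in the extracellular
#' compartment and a product elsewhere.
#'
#' @param network A `metabolite_network` built by [build_network()].
#' @param reactions The reaction set the network was built from; defaults
#'   to the one stored in the network.
#' @param extracellular Compartment code of the extracellular space
#'   (default `"e"`).
#' @return Data frame with one row per link: `from`, `to`,
#'   `reaction_class` (semicolon-joined sorted class labels),
#'   `n_classes`, `is_transport`, `crosses_into_cell`.
#' @export
link_annotation_table <- function(network, reactions = network$reactions,
                                  extracellular = "e") {
  if (is.null(network$link_reactions))
    stop("network has no inducing-reaction records; was it built from reactions?")
  rx <- stats::setNames(reactions, vapply(reactions, `[[`, character(1), "id"))
  env_to_cell <- function(r) {
    comps_s <- met_compartment(r$substrates)
    comps_p <- met_compartment(r$products)
    fwd <- any(comps_s == extracellular) && any(comps_p != extracellular)
    if (r$reversible)
      fwd <- fwd || (any(comps_p == extracellular) && any(comps_s != extracellular))
    fwd
  }
  n <- n_links(network)
  cls <- character(n); ncls <- integer(n)
  tr <- logical(n); cic <- logical(n)
  for (i in seq_len(n)) {
    rids <- network$link_reactions[[i]]
    if (is.null(rids) || length(rids) == 0L)
      stop("internal consistency error: link ", network$links$from[i],
           " -> ", network$links$to[i], " has no inducing reaction")
    rs <- rx[rids]
    labs <- sort(unique(vapply(rs, `[[`, character(1), "reaction_class")))
    cls[i] <- paste(labs, collapse = ";")
    ncls[i] <- length(labs)
    tr[i] <- any(vapply(rs, `[[`, logical(1), "is_transport"))
    cic[i] <- any(vapply(rs, env_to_cell, logical(1)))
  }
  data.frame(from = network$links$from, to = network$links$to,
             reaction_class = cls, n_classes = ncls,
             is_transport = tr, crosses_into_cell = cic,
             stringsAsFactors = FALSE)
}
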