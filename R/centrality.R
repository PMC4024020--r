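#' Centrality profile of a directed network
#'
#' Computes, per node: total, in- and out-degree; betweenness over
#' directed shortest paths, `B_v = sum_{s!=v!=t} sigma_st(v)/sigma_st`
#' (unnormalized, endpoints excluded); out-closeness and in-closeness as
#' reciprocal-distance sums over directed distances,
#' `C_out(v) = sum_i 1/d(v,i)` and `C_in(v) = sum_i 1/d(i,v)` (the
#' harmonic form: unreachable pairs contribute 0); and closeness, the same
#' sum over the undirected projection. A `"classical"` switch replaces the
#' three closeness columns by `1 / sum_i d(.,.)` computed within reachable
#' sets, for comparison.
#'
#' @param network A `metabolite_network`.
#' @param closeness One of `"harmonic"` (default) or `"classical"`.
#' @return Data frame of class `"centrality_profile"`: `node`, `D`,
#'   `InD`, `OutD`, `B`, `C_out`, `C_in`, `C`.
#' @examples
#' compute_centralities(edge_network(c("a", "b"), c("b", "c")))
#' @export
compute_centralities <- function(network,
                                 closeness = c("harmonic", "classical")) {
  closeness <- match.arg(closeness)
  g <- as_igraph(network)
  gu <- as_igraph(network, directed = FALSE)
  n <- n_nodes(network)
  B <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  if (closeness == "harmonic") {
    if (n > 1L) {
      c_out <- igraph::harmonic_centrality(g, mode = "out", normalized = FALSE)
      c_in <- igraph::harmonic_centrality(g, mode = "in", normalized = FALSE)
      c_all <- igraph::harmonic_centrality(gu, mode = "all", normalized = FALSE)
    } else c_out <- c_in <- c_all <- 0
  } else {
    cl <- function(gr, mode) {
      x <- suppressWarnings(igraph::closeness(gr, mode = mode))
      ifelse(is.finite(x), x, 0)
    }
    c_out <- cl(g, "out"); c_in <- cl(g, "in"); c_all <- cl(gu, "all")
  }
  structure(data.frame(
    node = network$nodes,
    D = igraph::degree(g, mode = "all"),
    InD = igraph::degree(g, mode = "in"),
    OutD = igraph::degree(g, mode = "out"),
    B = B, C_out = c_out, C_in = c_in, C = c_all,
    stringsAsFactors = FALSE, row.names = NULL),
    class = c("centrality_profile", "data.frame"))
}

#' Split nodes into low / medium / high score tertiles
#'
#' Sorts the nodes by score (ties broken by node id), cuts at the N/3 and
#' 2N/3 ranks, and moves any tie group that straddles a cut entirely into
#' the lower bin, so equal scores never end up in different bins.
#'
#' @param scores Named numeric vector (names = node ids), at least 3
#'   nodes.
#' @return List of class `"tertile_family"` with character vectors `low`,
#'   `medium`, `high` partitioning the nodes.
#' @export
tertile_split <- function(scores) {
  if (length(scores) < 3L) stop("need at least 3 nodes to form tertiles")
  if (is.null(names(scores))) stop("scores must be named by node id")
  o <- order(scores, names(scores))
  s <- scores[o]; ids <- names(scores)[o]
  N <- length(s)
  cut_at <- function(b) {   # extend b upward past any straddling tie group
    while (b >= 1L && b < N && s[b] == s[b + 1L]) b <- b + 1L
    b
  }
  b1 <- cut_at(N %/% 3L)
  b2 <- cut_at(max(b1, (2L * N) %/% 3L))
  if (b1 >= N || b2 >= N)
    warning("ties collapse one or more tertile boundaries; bins are uneven")
  structure(list(low = ids[seq_len(b1)],
                 medium = if (b2 > b1) ids[(b1 + 1L):b2] else character(0),
                 high = if (b2 < N) ids[(b2 + 1L):N] else character(0)),
            class = "tertile_family")
}

#' Fractions of a node set across centrality tertiles
#'
#' For a node set `A` and each tertile family `{X_l, X_m, X_h}`, reports
#' `|A n X_l|/|A|`, `|A n X_m|/|A|`, `|A n X_h|/|A|`, together with the
#' intersection counts (the observed data for [chi_square()]).
#'
#' @param node_set Character vector of node ids (non-empty).
#' @param families A named list of `"tertile_family"` objects (or a single
#'   one).
#' @return Data frame: `family`, `n_low`, `n_medium`, `n_high`,
#'   `frac_low`, `frac_medium`, `frac_high`.
#' @export
fraction_profile <- function(node_set, families) {
  if (length(node_set) == 0L) stop("empty node set")
  if (inherits(families, "tertile_family")) families <- list(families)
  if (is.null(names(families)))
    names(families) <- paste0("family", seq_along(families))
  rows <- lapply(names(families), function(fn) {
    fam <- families[[fn]]
    nl <- sum(node_set %in% fam$low)
    nm <- sum(node_set %in% fam$medium)
    nh <- sum(node_set %in% fam$high)
    data.frame(family = fn, n_low = nl, n_medium = nm, n_high = nh,
               frac_low = nl / length(node_set),
               frac_medium = nm / length(node_set),
               frac_high = nh / length(node_set),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
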