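# Brute-force oracles, independent of the package's algorithms. All work
# on tiny graphs only (exhaustive enumeration).

# every matching of the bipartite transform of `network`, as a list of
# integer edge-index vectors (indices into the bipartite edge list)
enumerate_matchings <- function(network) {
  bip <- to_bipartite(network)
  ne <- length(bip$eplus)
  out <- list(integer(0))
  if (ne == 0L) return(out)
  rec <- function(i, used_plus, used_minus, chosen) {
    if (i > ne) return(list(chosen))
    res <- rec(i + 1L, used_plus, used_minus, chosen)  # skip edge i
    u <- bip$eplus[i]; v <- bip$eminus[i]
    if (!u %in% used_plus && !v %in% used_minus)
      res <- c(res, rec(i + 1L, c(used_plus, u), c(used_minus, v),
                        c(chosen, i)))
    res
  }
  rec(1L, integer(0), integer(0), integer(0))
}

enumerate_maximum_matchings <- function(network) {
  all_m <- enumerate_matchings(network)
  sizes <- lengths(all_m)
  all_m[sizes == max(sizes)]
}

# drivers of one maximum matching: nodes whose minus copy is uncovered;
# `pad` applies the one-driver convention for perfect matchings
oracle_drivers <- function(network, matching_edges, pad = TRUE) {
  bip <- to_bipartite(network)
  covered <- bip$eminus[matching_edges]
  d <- bip$nodes[!seq_along(bip$nodes) %in% covered]
  if (pad && length(d) == 0L) d <- bip$nodes[1L]
  sort(d)
}

oracle_all_mdms <- function(network, pad = TRUE) {
  mm <- enumerate_maximum_matchings(network)
  unique(lapply(mm, function(m) oracle_drivers(network, m, pad = pad)))
}

# node control classes by exhaustive enumeration of unmatched-node sets
# (no padding: a perfectly matched network has no structural drivers, so
# every node classifies as redundant)
oracle_node_classes <- function(network) {
  mdms <- oracle_all_mdms(network, pad = FALSE)
  sapply(network$nodes, function(v) {
    inn <- vapply(mdms, function(s) v %in% s, logical(1))
    if (all(inn)) "critical" else if (any(inn)) "intermittent" else "redundant"
  })
}

# link classes by membership across all maximum matchings
oracle_link_classes <- function(network) {
  bip <- to_bipartite(network)
  mm <- enumerate_maximum_matchings(network)
  links <- network$links[!network$links$self_loop, , drop = FALSE]
  key_e <- paste(bip$nodes[bip$eplus], bip$nodes[bip$eminus])
  cls <- vapply(seq_along(key_e), function(i) {
    inn <- vapply(mm, function(m) i %in% m, logical(1))
    if (all(inn)) "critical" else if (any(inn)) "ordinary" else "redundant"
  }, character(1))
  stats::setNames(cls, paste(bip$nodes[bip$eplus], "->",
                             bip$nodes[bip$eminus]))
}

# exact driver frequencies over all distinct MDMSs
oracle_driver_frequency <- function(network) {
  mdms <- oracle_all_mdms(network)
  sapply(network$nodes, function(v)
    mean(vapply(mdms, function(s) v %in% s, logical(1))))
}

# betweenness per the shortest-path-count definition, by path enumeration
oracle_betweenness <- function(network) {
  g <- as_igraph(network)
  n <- length(network$nodes)
  B <- stats::setNames(numeric(n), network$nodes)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    sp <- suppressWarnings(igraph::all_shortest_paths(g, s, t, mode = "out"))
    paths <- sp$vpaths %||% sp$res
    if (length(paths) == 0L) next
    inner <- unlist(lapply(paths, function(p) setdiff(as.integer(p), c(s, t))))
    if (length(inner))
      for (v in inner) B[v] <- B[v] + 1 / length(paths)
  }
  B
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small directed network (no self-loops), seeded by caller
random_small_network <- function(n, p) {
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, ]
  keep <- stats::runif(nrow(pairs)) < p
  ids <- letters[seq_len(n)]
  if (!any(keep)) keep[sample.int(length(keep), 1L)] <- TRUE
  edge_network(ids[pairs$i[keep]], ids[pairs$j[keep]], nodes = ids)
}

# normalized mutual information between two labelings
nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- sqrt(h(pi) * h(pj))
  if (denom == 0) as.numeric(mi == 0) else mi / denom
}
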