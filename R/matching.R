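#' Bipartite transform of a directed network
#'
#' Every node `x` of the network is split into an out-copy `x+` and an
#' in-copy `x-`; every directed link `x -> y` becomes the undirected
#' bipartite edge `(x+, y-)`. Maximum matchings of this bipartite graph are
#' exactly the link sets of the directed network that share no start and no
#' end nodes, the object structural controllability analysis is built on.
#'
#' @param network A `metabolite_network`.
#' @param include_self_loops Keep self-loop links as bipartite edges
#'   `(x+, x-)`. Default `FALSE`: a self-loop trivially matches its own
#'   node, which is not an influence between distinct metabolites.
#' @return List of class `"bipartite_graph"` with `n` (node count),
#'   `nodes` (ids), and integer edge endpoint vectors `eplus`, `eminus`
#'   (edge `i` joins node `eplus[i]`'s plus copy to node `eminus[i]`'s
#'   minus copy).
#' @export
to_bipartite <- function(network, include_self_loops = FALSE) {
  links <- network$links
  if (!include_self_loops) links <- links[!links$self_loop, , drop = FALSE]
  structure(list(
    n = n_nodes(network),
    nodes = network$nodes,
    eplus = match(links$from, network$nodes),
    eminus = match(links$to, network$nodes)),
    class = "bipartite_graph")
}

# Hopcroft-Karp maximum bipartite matching. Layered BFS from free plus
# nodes, then DFS along the layering; repeats until no augmenting path
# exists. `edge_order` permutes adjacency construction — different orders
# can yield different (equally sized) matchings, which is the sampling
# handle used by sample_mdms().
hopcroft_karp <- function(bip, edge_order = seq_along(bip$eplus)) {
  n <- bip$n
  ep <- bip$eplus[edge_order]
  em <- bip$eminus[edge_order]
  # adjacency: minus neighbours of each plus node, in edge order
  adj <- split(em, factor(ep, levels = seq_len(n)))
  match_plus <- integer(n)   # plus u -> matched minus (0 = free)
  match_minus <- integer(n)  # minus v -> matched plus (0 = free)
  INF <- .Machine$integer.max
  repeat {
    # BFS: layer free plus nodes at 0
    dist <- rep.int(INF, n)
    queue <- which(match_plus == 0L & lengths(adj) > 0L)
    dist[queue] <- 0L
    found_free <- FALSE
    while (length(queue)) {
      nxt <- integer(0)
      for (u in queue) {
        for (v in adj[[u]]) {
          w <- match_minus[v]
          if (w == 0L) {
            found_free <- TRUE
          } else if (dist[w] == INF) {
            dist[w] <- dist[u] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      queue <- nxt
    }
    if (!found_free) break
    # DFS augmentation along strictly increasing layers
    for (root in which(match_plus == 0L & lengths(adj) > 0L)) {
      if (hk_dfs(root, adj, environment())) NULL
    }
  }
  list(match_plus = match_plus, match_minus = match_minus,
       size = sum(match_plus != 0L))
}

# recursive DFS step; mutates match_plus/match_minus/dist in `env`
hk_dfs <- function(u, adj, env) {
  for (v in adj[[u]]) {
    w <- env$match_minus[v]
    if (w == 0L ||
        (env$dist[w] == env$dist[u] + 1L && hk_dfs(w, adj, env))) {
      env$match_plus[u] <- v
      env$match_minus[v] <- u
      return(TRUE)
    }
  }
  env$dist[u] <- .Machine$integer.max  # dead end: prune
  FALSE
}

#' Maximum matching of a directed network
#'
#' Runs Hopcroft-Karp on the bipartite transform. The matching size is
#' independent of `edge_order`; the matched set itself may not be, which is
#' what [sample_mdms()] exploits.
#'
#' @inheritParams to_bipartite
#' @param edge_order Integer permutation of the bipartite edges; default
#'   the natural order.
#' @param seed If non-`NULL`, shuffle the edge order with this seed
#'   (overrides `edge_order`).
#' @return Object of class `"matching"`: `size`, `match_plus`,
#'   `match_minus` (integer maps by node index, 0 = unmatched), `nodes`,
#'   and `matched_links` (data frame of the matched directed links).
#' @examples
#' m <- maximum_matching(edge_network(c("a", "b"), c("b", "c")))
#' m$size  # 2
#' @export
maximum_matching <- function(network, edge_order = NULL, seed = NULL,
                             include_self_loops = FALSE) {
  bip <- to_bipartite(network, include_self_loops)
  ne <- length(bip$eplus)
  if (!is.null(seed)) edge_order <- with_seed(seed, sample.int(ne))
  if (is.null(edge_order)) edge_order <- seq_len(ne)
  stopifnot(length(edge_order) == ne)
  hk <- hopcroft_karp(bip, edge_order)
  mp <- hk$match_plus
  matched <- which(mp != 0L)
  structure(list(
    size = hk$size,
    match_plus = mp,
    match_minus = hk$match_minus,
    nodes = bip$nodes,
    matched_links = data.frame(from = bip$nodes[matched],
                               to = bip$nodes[mp[matched]],
                               stringsAsFactors = FALSE)),
    class = "matching")
}

#' @export
print.matching <- function(x, ...) {
  cat("Maximum matching: size", x$size, "on", length(x$nodes), "nodes;",
      sum(x$match_minus == 0L), "unmatched (driver) nodes\n")
  invisible(x)
}

# TRUE iff the matching stored in `hk`-style vectors admits an augmenting
# path, i.e. is not maximum
has_augmenting_path <- function(bip, match_plus, match_minus) {
  n <- bip$n
  adj <- split(bip$eminus, factor(bip$eplus, levels = seq_len(n)))
  dist <- rep.int(NA_integer_, n)
  queue <- which(match_plus == 0L & lengths(adj) > 0L)
  dist[queue] <- 0L
  while (length(queue)) {
    nxt <- integer(0)
    for (u in queue) {
      for (v in adj[[u]]) {
        w <- match_minus[v]
        if (w == 0L) return(TRUE)
        if (is.na(dist[w])) { dist[w] <- dist[u] + 1L; nxt <- c(nxt, w) }
      }
    }
    queue <- nxt
  }
  FALSE
}

#' Minimum driver-metabolite set induced by a maximum matching
#'
#' The drivers are the nodes whose in-copy is unmatched: injecting an
#' independent input at each renders the network structurally controllable.
#' For a perfect matching the set would be empty, but one input is always
#' needed, so the first node in canonical id order is returned; the driver
#' count therefore equals `max(N - |M|, 1)`.
#'
#' @param network A `metabolite_network`.
#' @param matching A maximum [maximum_matching()] of `network`.
#' @return Character vector of driver node ids (an MDMS).
#' @export
mdms_from_matching <- function(network, matching) {
  stopifnot(inherits(matching, "matching"),
            identical(matching$nodes, network$nodes))
  bip <- to_bipartite(network)
  if (has_augmenting_path(bip, matching$match_plus, matching$match_minus))
    stop("matching is not maximum: an augmenting path exists")
  drivers <- matching$nodes[matching$match_minus == 0L]
  if (length(drivers) == 0L) drivers <- matching$nodes[1L]
  drivers
}

#' Sample distinct minimum driver-metabolite sets
#'
#' Repeatedly shuffles the bipartite edge list, recomputes a maximum
#' matching with Hopcroft-Karp, extracts the induced MDMS, and keeps the
#' distinct driver sets (every pair of retained MDMSs differs). Sampling
#' stops once `n_samples` distinct MDMSs are found or an attempt budget of
#' `max_tries` shuffles is exhausted, in which case all distinct sets found
#' so far are returned with a warning.
#'
#' @inheritParams mdms_from_matching
#' @param n_samples Number of distinct MDMSs requested.
#' @param seed Integer seed; the whole sample sequence is reproducible.
#' @param max_tries Attempt budget (default `10 * n_samples`).
#' @return List of class `"mdms_sample"`: character-vector MDMSs, with
#'   attributes `matching_size`, `n_attempts`, `n_distinct_matchings`,
#'   `n_distinct_mdms` and `seed`.
#' @export
sample_mdms <- function(network, n_samples, seed = 1L,
                        max_tries = 10L * n_samples) {
  if (n_samples < 1L) stop("n_samples must be at least 1")
  bip <- to_bipartite(network)
  ne <- length(bip$eplus)
  with_seed(seed, {
    seen_mdms <- character(0)
    seen_matchings <- character(0)
    out <- vector("list", n_samples)
    k <- 0L; tries <- 0L; msize <- NA_integer_
    while (k < n_samples && tries < max_tries) {
      tries <- tries + 1L
      hk <- hopcroft_karp(bip, if (ne > 0L) sample.int(ne) else integer(0))
      msize <- hk$size
      mkey <- paste(hk$match_minus, collapse = ",")
      if (!mkey %in% seen_matchings)
        seen_matchings <- c(seen_matchings, mkey)
      drivers <- bip$nodes[hk$match_minus == 0L]
      if (length(drivers) == 0L) drivers <- bip$nodes[1L]
      dkey <- paste(sort(drivers), collapse = "|")
      if (!dkey %in% seen_mdms) {
        seen_mdms <- c(seen_mdms, dkey)
        k <- k + 1L
        out[[k]] <- sort(drivers)
      }
    }
    if (k < n_samples)
      warning("found only ", k, " distinct MDMSs in ", tries,
              " attempts (requested ", n_samples, ")")
    structure(out[seq_len(k)], class = "mdms_sample",
              matching_size = msize, n_attempts = tries,
              n_distinct_matchings = length(seen_matchings),
              n_distinct_mdms = k, seed = seed)
  })
}

#' Driver frequencies and driver classes
#'
#' For each node, the fraction of sampled MDMSs it appears in, and the
#' induced class: `critical` at frequency exactly 1, `high_frequency` on
#' `[0.6, 1)`, `low_frequency` on `[0, 0.6)`. Frequencies are compared as
#' exact integer ratios, so the interval boundaries are honoured without
#' floating-point slack.
#'
#' @param samples An `"mdms_sample"` (or plain list of character-vector
#'   driver sets).
#' @param nodes Node universe; defaults to the union of the samples.
#' @return Data frame of class `"driver_frequency"`: `node`, `count`,
#'   `f_d`, `class`, ordered by decreasing frequency then id; attribute
#'   `sample_count` holds the denominator (number of distinct MDMSs).
#' @export
driver_frequency <- function(samples, nodes = NULL) {
  if (length(samples) == 0L) stop("empty MDMS sample")
  nodes <- sort(unique(c(nodes, unlist(samples))))
  nsamp <- length(samples)
  counts <- table(factor(unlist(samples), levels = nodes))
  cnt <- as.integer(counts)
  cls <- ifelse(cnt == nsamp, "critical",
         ifelse(5L * cnt >= 3L * nsamp, "high_frequency", "low_frequency"))
  out <- data.frame(node = nodes, count = cnt, f_d = cnt / nsamp,
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(-out$f_d, out$node), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("driver_frequency", "data.frame"),
            sample_count = nsamp)
}
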