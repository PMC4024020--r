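#' Exact node control classes
#'
#' Classifies every node as `critical`, `intermittent` or `redundant`
#' according to whether it is a driver in all, some, or none of the minimum
#' driver sets — without enumerating maximum matchings. Two structural
#' facts make this exact: a node's in-copy with at least one incoming link
#' is matched in some maximum matching (an exchange argument on any
#' maximum matching), so a node is critical if and only if its in-degree
#' is zero; and given one maximum matching, a matched in-copy is avoidable
#' (the node is a driver in some MDMS) exactly when it is reachable from a
#' free in-copy along an alternating path (free edge out of a minus node,
#' matching edge out of a plus node).
#'
#' @param network A `metabolite_network`. Self-loops are ignored, as in
#'   [maximum_matching()].
#' @return Data frame `node`, `class` plus attribute `n_r`, the fraction
#'   of redundant nodes.
#' @examples
#' exact_node_control_class(edge_network(c("a", "b"), c("b", "c")))
#' @export
exact_node_control_class <- function(network) {
  bip <- to_bipartite(network)
  n <- bip$n
  hk <- hopcroft_karp(bip)
  # alternating-path reachability over minus copies:
  # minus v -(free edge)-> plus u -(matching edge)-> minus match_plus[u]
  indeg <- tabulate(bip$eminus, nbins = n)
  free_minus <- hk$match_minus == 0L
  reach <- free_minus
  # free bipartite edges grouped by their minus endpoint
  is_matched_edge <- hk$match_plus[bip$eplus] == bip$eminus
  free_plus_of <- split(bip$eplus[!is_matched_edge],
                        factor(bip$eminus[!is_matched_edge], levels = seq_len(n)))
  queue <- which(free_minus)
  while (length(queue)) {
    nxt <- integer(0)
    for (v in queue) {
      for (u in free_plus_of[[v]]) {
        w <- hk$match_plus[u]
        if (w != 0L && !reach[w]) { reach[w] <- TRUE; nxt <- c(nxt, w) }
      }
    }
    queue <- nxt
  }
  cls <- ifelse(indeg == 0L, "critical",
         ifelse(reach, "intermittent", "redundant"))
  out <- data.frame(node = bip$nodes, class = cls, stringsAsFactors = FALSE)
  structure(out, class = c("control_class", "data.frame"),
            n_r = mean(cls == "redundant"))
}

#' Control mode of a network
#'
#' Compares the fraction of redundant nodes `n_r` in the network with the
#' same fraction in its transpose (all links reversed). A positive
#' difference marks a centralized network, a negative one a distributed
#' network; zero is reported as indeterminate.
#'
#' @param network A `metabolite_network`.
#' @return List of class `"control_mode"`: `node_class` (data frame from
#'   [exact_node_control_class()]), `n_r`, `n_r_T`, `delta_n_r`, `mode`.
#' @export
control_mode <- function(network) {
  cc <- exact_node_control_class(network)
  cc_t <- exact_node_control_class(transpose_network(network))
  n_r <- attr(cc, "n_r"); n_r_t <- attr(cc_t, "n_r")
  d <- n_r - n_r_t
  structure(list(node_class = cc, n_r = n_r, n_r_T = n_r_t, delta_n_r = d,
                 mode = if (d > 0) "centralized"
                        else if (d < 0) "distributed"
                        else "indeterminate"),
            class = "control_mode")
}

#' @export
print.control_mode <- function(x, ...) {
  cat(sprintf("Control mode: %s (n_r = %.4f, n_r^T = %.4f, delta = %+.4f)\n",
              x$mode, x$n_r, x$n_r_T, x$delta_n_r))
  invisible(x)
}
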