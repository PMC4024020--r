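#' Node role cartography from a module partition
#'
#' For every node the within-module degree `z` (the z-score of its link
#' count into its own module, over the nodes of that module) and the
#' participation coefficient `P = 1 - sum_s (k_is / k_i)^2` are computed on
#' the undirected projection, and a role is assigned:
#' non-hubs (`z < 2.5`) are R1 (`P <= 0.05`, links confined to the own
#' module), R2 (`0.05 < P <= 0.62`), R3 (`0.62 < P <= 0.80`) or R4
#' (`P > 0.80`); hubs (`z >= 2.5`) are R5 (`P <= 0.30`), R6
#' (`0.30 < P <= 0.75`) or R7 (`P > 0.75`).
#'
#' Degenerate cases: a module whose nodes all have the same within-degree
#' has zero spread, and its nodes get `z = 0`; an isolated node (`k = 0`)
#' gets `P = 0`, `z = 0` and role R1. The within-module spread is the
#' population standard deviation.
#'
#' @param network A `metabolite_network`.
#' @param partition An `"sa_partition"` or a membership vector named by
#'   node id.
#' @return Data frame of class `"role_table"`: `node`, `module`, `degree`,
#'   `within_degree`, `z`, `P`, `role`.
#' @export
assign_roles <- function(network, partition) {
  mem <- if (inherits(partition, "sa_partition")) partition$membership
         else partition
  mem <- align_membership(mem, network$nodes)
  ua <- undirected_adjacency(network)
  n <- ua$n
  n_mod <- max(mem)
  # k_is: links of node i into module s
  kis <- matrix(0L, n, n_mod)
  for (i in seq_len(n)) {
    tb <- tabulate(mem[ua$adj[[i]]], nbins = n_mod)
    kis[i, ] <- tb
  }
  k <- ua$deg
  kw <- kis[cbind(seq_len(n), mem)]           # within-module degree
  z <- numeric(n)
  for (s in seq_len(n_mod)) {
    ids <- which(mem == s)
    mu <- mean(kw[ids])
    sg <- sqrt(mean((kw[ids] - mu)^2))        # population sd
    z[ids] <- if (sg > 0) (kw[ids] - mu) / sg else 0
  }
  P <- ifelse(k == 0, 0, 1 - rowSums((kis / pmax(k, 1L))^2))
  role <- role_from_zp(z, P)
  structure(data.frame(node = network$nodes, module = mem, degree = k,
                       within_degree = kw, z = z, P = P, role = role,
                       stringsAsFactors = FALSE),
            class = c("role_table", "data.frame"))
}

# pure function of (z, P); classical cartography thresholds, inclusive on
# the left class (P <= 0.05 is R1, etc.)
role_from_zp <- function(z, P) {
  ifelse(z < 2.5,
         ifelse(P <= 0.05, "R1",
         ifelse(P <= 0.62, "R2",
         ifelse(P <= 0.80, "R3", "R4"))),
         ifelse(P <= 0.30, "R5",
         ifelse(P <= 0.75, "R6", "R7")))
}

#' Role stability across repeated annealing runs
#'
#' Repeats module detection with distinct seeds and reports, per node, the
#' empirical probability of landing in each role.
#'
#' @param network A `metabolite_network`.
#' @param n_runs Number of independent SA runs (at least 2).
#' @param config Base [sa_config()]; run `i` uses seed `config$seed + i - 1`.
#' @return Matrix nodes x roles (R1..R7) of probabilities; rows sum to 1.
#' @export
role_frequency_stability <- function(network, n_runs, config = sa_config()) {
  stopifnot(n_runs >= 2L)
  roles <- c("R1", "R2", "R3", "R4", "R5", "R6", "R7")
  acc <- matrix(0, n_nodes(network), length(roles),
                dimnames = list(network$nodes, roles))
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    rt <- assign_roles(network, simulated_annealing(network, cfg))
    acc[cbind(rt$node, rt$role)] <- acc[cbind(rt$node, rt$role)] + 1
  }
  acc / n_runs
}

#' Role composition of high-frequency driver sets
#'
#' For each threshold `f_dt` in a grid, takes the set of nodes with driver
#' frequency `f_dt <= f_d < 1` and reports the fraction of each role in
#' it. This is the sweep used to separate high- from low-frequency
#' drivers: the threshold where the role mix changes most sharply.
#'
#' @param role_table A `"role_table"` from [assign_roles()].
#' @param frequency_table A `"driver_frequency"` over the same nodes.
#' @param thresholds Numeric grid of `f_dt` values.
#' @return Data frame: `f_dt`, `n_nodes`, then one fraction column per
#'   role (NA when the set is empty).
#' @export
driver_role_profile <- function(role_table, frequency_table,
                                thresholds = seq(0, 0.9, by = 0.1)) {
  if (!setequal(role_table$node, frequency_table$node))
    stop("role table and frequency table cover different node sets")
  roles <- c("R1", "R2", "R3", "R4", "R5", "R6", "R7")
  f_d <- frequency_table$f_d[match(role_table$node, frequency_table$node)]
  rows <- lapply(thresholds, function(t) {
    sel <- f_d >= t & f_d < 1
    n <- sum(sel)
    fr <- if (n == 0L) rep(NA_real_, length(roles))
          else as.numeric(table(factor(role_table$role[sel],
                                       levels = roles))) / n
    data.frame(f_dt = t, n_nodes = n,
               t(stats::setNames(fr, roles)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
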