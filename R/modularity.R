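# Modularity and its simulated-annealing optimiser operate on the
# undirected simple projection of the network: link directions are dropped,
# reciprocal links collapse to one undirected link, self-loops are removed.

# undirected adjacency list by node index, plus degree vector
undirected_adjacency <- function(network) {
  a <- match(network$links$from, network$nodes)
  b <- match(network$links$to, network$nodes)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(lo * (length(network$nodes) + 1) + hi)
  lo <- lo[keep]; hi <- hi[keep]
  n <- length(network$nodes)
  adj <- split(c(hi, lo), factor(c(lo, hi), levels = seq_len(n)))
  list(n = n, adj = adj, deg = lengths(adj), L = length(lo),
       elo = lo, ehi = hi)
}

#' Modularity of a partition
#'
#' The modularity of a module assignment is the summed gap, over modules,
#' between the fraction of links inside the module and the fraction
#' expected if links were wired at random with the same degrees:
#' `M = sum_s [ l_s / L - (d_s / 2L)^2 ]`, with `L` the undirected link
#' count, `l_s` the links within module `s` and `d_s` the total degree of
#' its nodes. Placing all nodes in a single module gives exactly 0.
#'
#' @param network A `metabolite_network`; treated as an undirected simple
#'   graph (directions dropped, reciprocal links merged, self-loops
#'   ignored).
#' @param membership Module assignment: named vector (names = node ids) or
#'   a vector aligned with `network$nodes`.
#' @return The modularity, a number in `[-1, 1)`.
#' @examples
#' net <- edge_network(c("a", "b", "c"), c("b", "c", "a"))
#' modularity_score(net, setNames(c(1, 1, 1), net$nodes))  # 0
#' @export
modularity_score <- function(network, membership) {
  ua <- undirected_adjacency(network)
  mem <- align_membership(membership, network$nodes)
  if (ua$L == 0L) return(0)
  within <- mem[ua$elo] == mem[ua$ehi]
  l_s <- tapply(within, mem[ua$elo], sum)      # within-links per module
  d_s <- tapply(ua$deg, mem, sum)              # degree sums per module
  l_full <- stats::setNames(numeric(length(d_s)), names(d_s))
  l_full[names(l_s)] <- l_s
  sum(l_full / ua$L - (d_s / (2 * ua$L))^2)
}

align_membership <- function(membership, nodes) {
  if (!is.null(names(membership))) {
    if (!all(nodes %in% names(membership)))
      stop("membership missing node(s): ",
           paste(utils::head(setdiff(nodes, names(membership)), 3L),
                 collapse = ", "))
    membership <- membership[nodes]
  } else if (length(membership) != length(nodes)) {
    stop("membership length does not match node count")
  }
  as.integer(factor(membership))
}

#' Simulated-annealing configuration
#'
#' @param f Iteration factor: each temperature evaluates `f * S^2`
#'   single-node moves and `f * S` collective moves (`S` = node count).
#' @param cooling Geometric cooling factor `c` in (0,1); after each
#'   temperature `T` becomes `c * T`.
#' @param t0 Initial temperature; `NULL` (default) calibrates it so that
#'   roughly 90 percent of initial uphill proposals are accepted.
#' @param t_min_ratio Stop when `T < t_min_ratio * t0`.
#' @param frozen_temps Also stop after this many consecutive temperatures
#'   without an accepted move.
#' @param seed Integer seed; the optimisation is reproducible.
#' @return List of class `"sa_config"`.
#' @export
sa_config <- function(f = 1, cooling = 0.965, t0 = NULL,
                      t_min_ratio = 1e-4, frozen_temps = 3L, seed = 1L) {
  stopifnot(f > 0, cooling > 0, cooling < 1,
            is.null(t0) || t0 > 0, t_min_ratio > 0, frozen_temps >= 1)
  structure(list(f = f, cooling = cooling, t0 = t0,
                 t_min_ratio = t_min_ratio, frozen_temps = frozen_temps,
                 seed = seed),
            class = "sa_config")
}

#' Module detection by simulated annealing
#'
#' Minimises `C = -M` (modularity `M` as in [modularity_score()]) by
#' simulated annealing. Starting from singleton modules at a high
#' temperature, each temperature evaluates `f*S^2` single-node moves and
#' `f*S` collective moves (merging two random modules, or splitting a
#' random module by bisection plus a short greedy refinement), accepting a
#' proposal with probability 1 if it does not increase `C` and
#' `exp(-(C_f - C_i)/T)` otherwise; `T` then cools geometrically by the
#' factor `c`. The best partition encountered is returned, never worse
#' than the single-module partition (`M >= 0`).
#'
#' @param network A `metabolite_network` (undirected projection is used).
#' @param config An [sa_config()].
#' @return List of class `"sa_partition"`: `membership` (named integer
#'   vector, consecutive module ids), `n_modules`, `modularity`,
#'   `n_temperatures`, `config`.
#' @examples
#' net <- generate_planted_network(planted_partition_spec(
#'   n_modules = 2, nodes_per_module = 6, p_within = 1, p_between = 0,
#'   seed = 1))$network
#' simulated_annealing(net, sa_config(seed = 1))$n_modules
#' @export
simulated_annealing <- function(network, config = sa_config()) {
  stopifnot(inherits(config, "sa_config"))
  ua <- undirected_adjacency(network)
  S <- ua$n
  if (S < 2L) stop("need at least 2 nodes")
  with_seed(config$seed, {
    st <- sa_run(ua, config)
    mem <- as.integer(factor(st$membership))
    structure(list(membership = stats::setNames(mem, network$nodes),
                   n_modules = max(mem),
                   modularity = st$modularity,
                   n_temperatures = st$n_temps,
                   config = config),
              class = "sa_partition")
  })
}

#' @export
print.sa_partition <- function(x, ...) {
  cat(sprintf("SA partition: %d modules, modularity %.4f (%d temperatures)\n",
              x$n_modules, x$modularity, x$n_temperatures))
  invisible(x)
}

# core annealing loop over a precomputed undirected adjacency; assumes the
# RNG is already seeded by the caller
sa_run <- function(ua, config) {
  S <- ua$n; L <- ua$L; adj <- ua$adj; deg <- ua$deg
  mem <- seq_len(S)                    # singleton start
  lvec <- numeric(2L * S)              # within-link count per module id
  dvec <- numeric(2L * S); dvec[seq_len(S)] <- deg
  n_mod <- S
  if (L == 0L)
    return(list(membership = rep(1L, S), modularity = 0, n_temps = 0L))

  # current M from the state vectors
  state_m <- function() sum(lvec) / L - sum((dvec / (2 * L))^2)

  # delta-M of moving node i from module a to module b
  move_delta <- function(i, a, b) {
    nb <- adj[[i]]
    mnb <- mem[nb]
    kia <- sum(mnb == a); kib <- sum(mnb == b)
    (kib - kia) / L -
      (2 * deg[i] * (dvec[b] - dvec[a]) + 2 * deg[i]^2) / (4 * L^2)
  }
  apply_move <- function(i, a, b) {
    nb <- adj[[i]]; mnb <- mem[nb]
    lvec[a] <<- lvec[a] - sum(mnb == a)
    lvec[b] <<- lvec[b] + sum(mnb == b)
    dvec[a] <<- dvec[a] - deg[i]; dvec[b] <<- dvec[b] + deg[i]
    mem[i] <<- b
  }

  mods <- function() unique(mem)

  # T0 calibration: accept ~90% of uphill single-node proposals
  t0 <- config$t0
  if (is.null(t0)) {
    ups <- numeric(0)
    ms <- mods()
    for (k in seq_len(min(100L, 10L * S))) {
      i <- sample.int(S, 1L)
      b <- ms[sample.int(length(ms), 1L)]
      if (b == mem[i]) next
      d <- move_delta(i, mem[i], b)
      if (d < 0) ups <- c(ups, -d)
    }
    t0 <- if (length(ups)) stats::median(ups) / log(1 / 0.9) else 1
  }

  n_i <- max(1L, ceiling(config$f * S^2))
  n_c <- max(1L, ceiling(config$f * S))
  temp <- t0
  best_mem <- mem; best_m <- state_m()
  frozen <- 0L; n_temps <- 0L

  while (temp >= config$t_min_ratio * t0 && frozen < config$frozen_temps) {
    n_temps <- n_temps + 1L
    accepted <- 0L
    ms <- mods()
    for (k in seq_len(n_i)) {
      i <- sample.int(S, 1L)
      a <- mem[i]
      b <- ms[sample.int(length(ms), 1L)]
      if (b == a) next
      d <- move_delta(i, a, b)
      if (d >= 0 || stats::runif(1) < exp(d / temp)) {
        apply_move(i, a, b)
        accepted <- accepted + 1L
        if (!any(mem == a)) ms <- mods()  # module a emptied
      }
    }
    # collective moves: random merges and splits
    for (k in seq_len(n_c)) {
      ms <- mods()
      if (stats::runif(1) < 0.5 && length(ms) >= 2L) {
        ab <- ms[sample.int(length(ms), 2L)]
        a <- ab[1L]; b <- ab[2L]
        nodes_a <- which(mem == a)
        e_ab <- sum(mem[unlist(adj[nodes_a], use.names = FALSE)] == b)
        d <- e_ab / L - 2 * dvec[a] * dvec[b] / (4 * L^2)
        if (d >= 0 || stats::runif(1) < exp(d / temp)) {
          lvec[b] <- lvec[b] + lvec[a] + e_ab
          dvec[b] <- dvec[b] + dvec[a]
          lvec[a] <- 0; dvec[a] <- 0
          mem[nodes_a] <- b
          accepted <- accepted + 1L
        }
      } else {
        a <- ms[sample.int(length(ms), 1L)]
        nodes_a <- which(mem == a)
        if (length(nodes_a) < 2L) next
        old <- list(mem = mem, lvec = lvec, dvec = dvec)
        m_before <- state_m()
        b <- setdiff(seq_len(2L * S), ms)[1L]  # unused module id
        half <- sample(nodes_a, ceiling(length(nodes_a) / 2))
        for (i in half) apply_move(i, a, b)
        # greedy refinement between the two halves
        for (pass in 1:2) {
          improved <- FALSE
          for (i in sample(nodes_a)) {
            cur <- mem[i]; oth <- if (cur == a) b else a
            if (move_delta(i, cur, oth) > 0) {
              apply_move(i, cur, oth); improved <- TRUE
            }
          }
          if (!improved) break
        }
        d <- state_m() - m_before
        if (d >= 0 || stats::runif(1) < exp(d / temp)) {
          accepted <- accepted + 1L
        } else {
          mem <- old$mem; lvec <- old$lvec; dvec <- old$dvec
        }
      }
    }
    m_now <- state_m()
    if (m_now > best_m) { best_m <- m_now; best_mem <- mem }
    frozen <- if (accepted == 0L) frozen + 1L else 0L
    temp <- temp * config$cooling
  }
  if (best_m < 0) {  # never worse than the single-module partition
    best_mem <- rep(1L, S); best_m <- 0
  }
  list(membership = best_mem, modularity = best_m, n_temps = n_temps)
}
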