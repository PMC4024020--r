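#' Full structural-controllability analysis of a metabolite network
#'
#' The package's main entry point. Runs, in order: maximum-matching driver
#' detection with MDMS sampling and driver-frequency classification
#' (critical / high-frequency / low-frequency at the 1 and 0.6 frequency
#' thresholds); exact node control classes and the control mode against
#' the transpose network; link robustness classification (critical /
#' ordinary / redundant) and, when the network was built from an annotated
#' reaction set, reaction-class enrichment with a chi-square test of the
#' critical-link composition against the whole-network composition;
#' centrality profiles with tertile binning and fraction profiles of the
#' driver union (set A) and the critical-plus-high-frequency set (set B),
#' each with a chi-square test against the uniform tertile split; and,
#' optionally, simulated-annealing module detection with role cartography
#' and the role profile of high-frequency driver sets.
#'
#' @param x A `metabolite_network`, or a `reaction_set` (then the network
#'   is built first and link annotations are available).
#' @param n_samples Distinct MDMSs to sample (default 5000).
#' @param seed Integer seed driving every stochastic stage.
#' @param alpha Significance level for the chi-square tests.
#' @param high_threshold Driver-frequency threshold separating high- from
#'   low-frequency drivers (default 0.6).
#' @param modules Run SA module detection and role assignment (default
#'   `TRUE`; the slowest stage).
#' @param sa An [sa_config()] for the module stage; its seed is derived
#'   from `seed` when left at the default.
#' @return Object of class `"netctrl"`; see the individual stage
#'   functions for the component formats. Print and summary methods give
#'   a compact report.
#' @examples
#' net <- fixture_gallery()$star4
#' fit <- netctrl(net, n_samples = 10, seed = 1, modules = FALSE)
#' fit$driver_frequency
#' @export
netctrl <- function(x, n_samples = 5000L, seed = 1L, alpha = 0.05,
                    high_threshold = 0.6, modules = TRUE,
                    sa = sa_config(seed = seed)) {
  if (inherits(x, "reaction_set")) {
    network <- build_network(x)
  } else if (inherits(x, "metabolite_network")) {
    network <- x
  } else stop("x must be a reaction_set or metabolite_network")

  samples <- sample_mdms(network, n_samples, seed = seed)
  freq <- driver_frequency(samples, nodes = network$nodes)
  cmode <- control_mode(network)
  link_cls <- classify_links(network)

  enrichment <- NULL; critical_link_test <- NULL
  if (!is.null(network$link_reactions)) {
    ann <- link_annotation_table(network)
    enrichment <- link_class_enrichment(link_cls, ann)
    cm <- enrichment$counts_multi
    obs <- cm["critical", c("core_high", "core_moderate", "non_core")]
    ens <- cm["Ensemble", c("core_high", "core_moderate", "non_core")]
    if (sum(obs) > 0 && all(ens > 0))
      critical_link_test <- chi_square(obs, ens / sum(ens), alpha = alpha)
  }

  centr <- compute_centralities(network)
  families <- NULL; profiles <- NULL; centrality_tests <- NULL
  if (n_nodes(network) >= 3L) {
    measures <- c("D", "InD", "OutD", "B", "C", "C_in", "C_out")
    families <- lapply(stats::setNames(measures, measures), function(m)
      tertile_split(stats::setNames(centr[[m]], centr$node)))
    set_a <- sort(unique(unlist(samples)))
    set_b <- freq$node[freq$class %in% c("critical", "high_frequency")]
    profiles <- list(
      A = fraction_profile(set_a, families),
      B = if (length(set_b)) fraction_profile(set_b, families) else NULL)
    centrality_tests <- lapply(profiles, function(pr) {
      if (is.null(pr)) return(NULL)
      lapply(stats::setNames(seq_len(nrow(pr)), pr$family), function(i) {
        obs <- as.integer(pr[i, c("n_low", "n_medium", "n_high")])
        fam <- families[[pr$family[i]]]
        p <- lengths(fam[c("low", "medium", "high")]) / sum(lengths(fam))
        if (all(p > 0)) chi_square(obs, p, alpha = alpha) else NULL
      })
    })
  }

  partition <- NULL; roles <- NULL; role_profile <- NULL
  if (modules && n_nodes(network) >= 2L) {
    partition <- simulated_annealing(network, sa)
    roles <- assign_roles(network, partition)
    role_profile <- driver_role_profile(roles, freq)
  }

  structure(list(
    network = network,
    matching_size = attr(samples, "matching_size"),
    samples = samples,
    driver_frequency = freq,
    control_mode = cmode,
    link_classes = link_cls,
    enrichment = enrichment,
    critical_link_test = critical_link_test,
    centrality = centr,
    tertiles = families,
    profiles = profiles,
    centrality_tests = centrality_tests,
    partition = partition,
    roles = roles,
    role_profile = role_profile,
    params = list(n_samples = n_samples, seed = seed, alpha = alpha,
                  high_threshold = high_threshold)),
    class = "netctrl")
}

#' @export
print.netctrl <- function(x, ...) {
  net <- x$network
  cat("Structural controllability analysis\n")
  cat(sprintf("  network: %d nodes, %d links\n", n_nodes(net), n_links(net)))
  cat(sprintf("  maximum matching size: %d  ->  %d driver nodes per MDMS\n",
              x$matching_size,
              max(n_nodes(net) - x$matching_size, 1L)))
  cat(sprintf("  distinct MDMSs sampled: %d (seed %d)\n",
              attr(x$samples, "n_distinct_mdms"), x$params$seed))
  cls <- table(factor(x$driver_frequency$class,
                      c("critical", "high_frequency", "low_frequency")))
  cat(sprintf("  driver classes: %d critical, %d high-frequency, %d low-frequency\n",
              cls[1], cls[2], cls[3]))
  cat(sprintf("  control mode: %s (delta n_r = %+.4f)\n",
              x$control_mode$mode, x$control_mode$delta_n_r))
  lc <- attr(x$link_classes, "counts")
  cat(sprintf("  link classes: %d critical, %d ordinary, %d redundant\n",
              lc["critical"], lc["ordinary"], lc["redundant"]))
  if (!is.null(x$partition))
    cat(sprintf("  modules: %d (modularity %.4f)\n",
                x$partition$n_modules, x$partition$modularity))
  invisible(x)
}

#' @export
summary.netctrl <- function(object, ...) {
  print(object)
  if (!is.null(object$critical_link_test)) {
    cat("\nCritical-link reaction-class composition vs whole network:\n  ")
    print(object$critical_link_test)
  }
  if (!is.null(object$roles)) {
    cat("\nRole distribution:\n")
    print(table(object$roles$role))
  }
  invisible(object)
}

#' Run the full pipeline from a configuration and write a report bundle
#'
#' Thin orchestration over [netctrl()]: reads a reaction list or edge
#' list, runs the analysis, and writes tab-separated stage outputs
#' (`drivers.tsv`, `links.tsv`, `centrality.tsv`, and `roles.tsv` when the
#' module stage runs) plus a `summary.json` capturing counts, fractions,
#' statistics and every seed, so a rerun with the same configuration
#' reproduces all numbers.
#'
#' @param config Named list (or path to a YAML file with these fields):
#'   `reactions` or `network` (input path), `outdir`, and optionally
#'   `samples` (default 5000), `seed` (1), `alpha` (0.05), `modules`
#'   (TRUE), `f` (1), `cooling` (0.965).
#' @return The `"netctrl"` object, invisibly; side effect: files under
#'   `config$outdir`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$outdir))
  x <- if (!is.null(config$reactions)) read_reactions(config$reactions)
       else if (!is.null(config$network)) read_edgelist(config$network)
       else stop("config needs a 'reactions' or 'network' input path")

  fit <- netctrl(x,
                 n_samples = as.integer(config$samples %||% 5000L),
                 seed = as.integer(config$seed %||% 1L),
                 alpha = config$alpha %||% 0.05,
                 modules = config$modules %||% TRUE,
                 sa = sa_config(f = config$f %||% 1,
                                cooling = config$cooling %||% 0.965,
                                seed = as.integer(config$seed %||% 1L)))

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$outdir, name)
  wt <- function(df, name)
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(fit$driver_frequency, "drivers.tsv")
  lk <- fit$link_classes
  if (!is.null(fit$enrichment)) {
    ann <- link_annotation_table(fit$network)
    lk <- cbind(lk, ann[match(link_key(lk$from, lk$to),
                              link_key(ann$from, ann$to)),
                        c("reaction_class", "is_transport")])
  }
  wt(lk, "links.tsv")
  wt(fit$centrality, "centrality.tsv")
  if (!is.null(fit$roles)) wt(fit$roles, "roles.tsv")

  summary <- list(
    seed = fit$params$seed,
    n_samples_requested = fit$params$n_samples,
    n_distinct_mdms = attr(fit$samples, "n_distinct_mdms"),
    n_distinct_matchings = attr(fit$samples, "n_distinct_matchings"),
    n_attempts = attr(fit$samples, "n_attempts"),
    matching_size = fit$matching_size,
    n_nodes = n_nodes(fit$network),
    n_links = n_links(fit$network),
    driver_classes = as.list(table(fit$driver_frequency$class)),
    link_classes = as.list(attr(fit$link_classes, "counts")),
    control_mode = fit$control_mode[c("n_r", "n_r_T", "delta_n_r", "mode")],
    critical_link_chi2 = if (!is.null(fit$critical_link_test))
      fit$critical_link_test[c("statistic", "df", "critical", "significant")],
    modularity = if (!is.null(fit$partition)) fit$partition$modularity,
    n_modules = if (!is.null(fit$partition)) fit$partition$n_modules)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(fit)
}
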