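#' Classify links by their role in controllability robustness
#'
#' Every link is `critical` (in every maximum matching: removing it raises
#' the number of required driver nodes), `redundant` (in no maximum
#' matching: removable without affecting the current driver set) or
#' `ordinary` (in some but not all). The classification uses Regin's
#' orientation argument, so only one maximum matching is needed: orient
#' matching edges plus-to-minus and free edges minus-to-plus (and the
#' reverse in a second orientation). A link is ordinary exactly when it
#' lies on an alternating path starting at a free node in either
#' orientation or inside a strongly connected component (an alternating
#' cycle); otherwise matched links are critical and free links redundant.
#' The result does not depend on which maximum matching is used.
#'
#' Self-loop links are excluded from the matching and classified
#' `ordinary` directly: a self-loop is its own alternating cycle.
#'
#' @param network A `metabolite_network`.
#' @param edge_order,seed Passed to the underlying matching; the class
#'   table is invariant to them (checked by the package's tests).
#' @return Data frame of class `"link_class_table"` with columns `from`,
#'   `to`, `link_class`; attribute `counts` holds the per-class totals.
#' @examples
#' classify_links(edge_network(c("a", "c"), c("b", "b")))  # both ordinary
#' @export
classify_links <- function(network, edge_order = NULL, seed = NULL) {
  links <- network$links
  nl <- nrow(links)
  cls <- rep.int(NA_character_, nl)
  cls[links$self_loop] <- "ordinary"
  idx <- which(!links$self_loop)

  if (length(idx)) {
    bip <- to_bipartite(network)
    ne <- length(bip$eplus)
    if (!is.null(seed)) edge_order <- with_seed(seed, sample.int(ne))
    if (is.null(edge_order)) edge_order <- seq_len(ne)
    hk <- hopcroft_karp(bip, edge_order)
    n <- bip$n
    matched_edge <- hk$match_plus[bip$eplus] == bip$eminus

    # vertex ids: plus copy u -> u, minus copy v -> n + v
    src1 <- ifelse(matched_edge, bip$eplus, n + bip$eminus)  # G_d1 sources
    dst1 <- ifelse(matched_edge, n + bip$eminus, bip$eplus)
    g1 <- igraph::graph_from_edgelist(cbind(src1, dst1))
    g1 <- igraph::add_vertices(g1, max(0L, 2L * n - igraph::vcount(g1)))
    g2 <- igraph::reverse_edges(g1)

    free_minus <- n + which(hk$match_minus == 0L)
    free_plus <- which(hk$match_plus == 0L)
    reach1 <- reachable_set(g1, free_minus)
    reach2 <- reachable_set(g2, free_plus)
    on_path <- reach1[src1] | reach2[dst1]  # dst1 is the G_d2 source

    comp1 <- igraph::components(g1, mode = "strong")$membership
    comp2 <- igraph::components(g2, mode = "strong")$membership
    # reversal preserves SCCs; assert as a cross-check
    stopifnot(all((comp1[src1] == comp1[dst1]) ==
                  (comp2[src1] == comp2[dst1])))
    csize <- tabulate(comp1)
    in_cycle <- comp1[src1] == comp1[dst1] & csize[comp1[src1]] > 1L

    ordinary <- on_path | in_cycle
    cls[idx] <- ifelse(ordinary, "ordinary",
                ifelse(matched_edge, "critical", "redundant"))
  }

  out <- data.frame(from = links$from, to = links$to, link_class = cls,
                    stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = c("critical", "ordinary", "redundant")))
  structure(out, class = c("link_class_table", "data.frame"),
            counts = counts)
}

reachable_set <- function(g, starts) {
  out <- logical(igraph::vcount(g))
  for (s in starts)  # union of out-subcomponents over all start nodes
    if (!out[s]) out[igraph::subcomponent(g, s, mode = "out")] <- TRUE
  out
}

#' Cross-tabulate link classes against reaction annotations
#'
#' For each robustness class and for the whole link set (`Ensemble`),
#' computes the fractions of links induced by core-high, core-moderate and
#' non-core reactions, the fraction of transport links, and the fraction of
#' links carrying metabolites from the extracellular space into the cell.
#' A link whose inducing reactions carry several class labels counts once
#' under each label (`multi` columns; fractions use label occurrences as
#' denominator); `strict` columns restrict to uniquely labelled links.
#' Observed counts are exported for [chi_square()].
#'
#' @param link_table A `"link_class_table"` from [classify_links()].
#' @param annotations Per-link attributes from [link_annotation_table()]
#'   over the same links.
#' @return List of class `"link_enrichment"`: `summary` (one row per link
#'   set with counts and fractions) and `counts_multi` / `counts_strict`
#'   (matrices link set x reaction class).
#' @export
link_class_enrichment <- function(link_table, annotations) {
  key_l <- link_key(link_table$from, link_table$to)
  key_a <- link_key(annotations$from, annotations$to)
  pos <- match(key_l, key_a)
  if (anyNA(pos))
    stop("annotation missing for classified link(s): ",
         paste(utils::head(key_l[is.na(pos)], 3L), collapse = ", "))
  ann <- annotations[pos, , drop = FALSE]

  classes <- c("core_high", "core_moderate", "non_core", "unlabeled")
  sets <- c(critical = "critical", ordinary = "ordinary",
            redundant = "redundant", Ensemble = NA)
  labs <- strsplit(ann$reaction_class, ";", fixed = TRUE)

  count_set <- function(sel, strict) {
    l <- labs[sel]
    if (strict) l <- l[lengths(l) == 1L]
    table(factor(unlist(l), levels = classes))
  }
  rows <- lapply(names(sets), function(s) {
    sel <- if (is.na(sets[[s]])) rep(TRUE, nrow(ann))
           else link_table$link_class == sets[[s]]
    nlk <- sum(sel)
    cm <- count_set(sel, strict = FALSE)
    csr <- count_set(sel, strict = TRUE)
    frac <- function(x) if (sum(x) == 0L) rep(NA_real_, length(x))
                        else as.numeric(x) / sum(x)
    data.frame(set = s, n_links = nlk,
               t(stats::setNames(as.integer(cm), paste0("n_", classes))),
               t(stats::setNames(frac(cm), paste0("frac_", classes))),
               frac_transport = if (nlk) mean(ann$is_transport[sel]) else NA_real_,
               frac_env_to_cell = if (nlk) mean(ann$crosses_into_cell[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  counts_multi <- t(vapply(names(sets), function(s) {
    sel <- if (is.na(sets[[s]])) rep(TRUE, nrow(ann))
           else link_table$link_class == sets[[s]]
    as.integer(count_set(sel, FALSE))
  }, integer(length(classes))))
  counts_strict <- t(vapply(names(sets), function(s) {
    sel <- if (is.na(sets[[s]])) rep(TRUE, nrow(ann))
           else link_table$link_class == sets[[s]]
    as.integer(count_set(sel, TRUE))
  }, integer(length(classes))))
  colnames(counts_multi) <- colnames(counts_strict) <- classes
  structure(list(summary = summary, counts_multi = counts_multi,
                 counts_strict = counts_strict),
            class = "link_enrichment")
}
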