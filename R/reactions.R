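#' Parse a compartmentalized reaction list
#'
#' Reads a plain-text reaction list in which every metabolite carries a
#' compartment tag, e.g. `h[c]` for a hydrogen ion in the cytoplasm, and the
#' same chemical species in two compartments counts as two distinct
#' metabolites. Two record formats are accepted, one per line:
#'
#' * the arrow dialect:
#'   `RID: a[c] + b[c] -> p[c] ; class=core_high ; rev=0`
#'   (`<->` marks a reversible reaction, equivalent to `rev=1`; the
#'   `class=` and `rev=` annotations are optional and may come in any order)
#' * a tab-separated form with columns
#'   `id`, `substrates`, `products`, `class`, `rev`, where the metabolite
#'   columns are `+`- or `,`-separated lists (last two columns optional).
#'
#' Blank lines and lines starting with `#` are skipped. Unannotated
#' reactions default to `unlabeled` class and irreversible. A reaction is a
#' transport reaction exactly when its substrates and products span at
#' least two distinct compartments; this is derived, never read from the
#' file.
#'
#' @param text Character vector of lines, or a single string containing
#'   newlines.
#' @return A list of reactions of class `"reaction_set"`. Each element has
#'   fields `id`, `substrates`, `products` (character vectors of
#'   `name[compartment]` ids), `reversible`, `reaction_class` (one of
#'   `core_high`, `core_moderate`, `non_core`, `unlabeled`) and
#'   `is_transport`.
#' @seealso [read_reactions()] to parse from a file, [build_network()] for
#'   the network construction rule.
#' @examples
#' rx <- parse_reactions(c(
#'   "R1: hgentis[c] + o2[c] -> 4mlacac[c] + h[c]",
#'   "R2: h[c] -> h[m]",
#'   "R3: h[m] + hco3[m] -> h2co3[m]"))
#' sapply(rx, `[[`, "is_transport")
#' @export
parse_reactions <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  reactions <- list()
  seen_ids <- character()
  for (ln in seq_along(text)) {
    line <- trimws(text[[ln]])
    if (line == "" || startsWith(line, "#")) next
    r <- if (grepl("\t", line, fixed = TRUE)) {
      parse_tabular_record(line, ln)
    } else {
      parse_arrow_record(line, ln)
    }
    if (r$id %in% seen_ids)
      stop("line ", ln, ": duplicate reaction id '", r$id, "'")
    seen_ids <- c(seen_ids, r$id)
    reactions[[length(reactions) + 1L]] <- r
  }
  structure(reactions, class = "reaction_set")
}

#' @rdname parse_reactions
#' @param path Path to a reaction-list file.
#' @export
read_reactions <- function(path) {
  parse_reactions(readLines(path, warn = FALSE))
}

parse_arrow_record <- function(line, ln) {
  parts <- strsplit(line, ";", fixed = TRUE)[[1L]]
  body <- trimws(parts[1L])
  anno <- trimws(parts[-1L])

  m <- regexpr(":", body, fixed = TRUE)
  if (m < 0) stop("line ", ln, ": missing 'ID:' prefix")
  id <- trimws(substr(body, 1L, m - 1L))
  if (id == "") stop("line ", ln, ": empty reaction id")
  eq <- trimws(substr(body, m + 1L, nchar(body)))

  reversible <- FALSE
  if (grepl("<->", eq, fixed = TRUE)) {
    sides <- strsplit(eq, "<->", fixed = TRUE)[[1L]]
    reversible <- TRUE
  } else if (grepl("->", eq, fixed = TRUE)) {
    sides <- strsplit(eq, "->", fixed = TRUE)[[1L]]
  } else {
    stop("line ", ln, ": no reaction arrow ('->' or '<->')")
  }
  if (length(sides) != 2L)
    stop("line ", ln, ": expected exactly one reaction arrow")

  cls <- "unlabeled"
  for (a in anno) {
    if (a == "") next
    kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (key == "class") {
      cls <- match_reaction_class(val, ln)
    } else if (key == "rev") {
      reversible <- reversible || val %in% c("1", "true", "TRUE")
    } # unknown annotations ignored
  }

  make_reaction(id,
                split_metabolites(sides[1L], ln),
                split_metabolites(sides[2L], ln),
                reversible, cls)
}

parse_tabular_record <- function(line, ln) {
  f <- trimws(strsplit(line, "\t", fixed = TRUE)[[1L]])
  if (length(f) < 3L)
    stop("line ", ln, ": tabular record needs at least id, substrates, products")
  cls <- if (length(f) >= 4L && f[4L] != "") match_reaction_class(f[4L], ln)
         else "unlabeled"
  rev <- length(f) >= 5L && f[5L] %in% c("1", "true", "TRUE")
  make_reaction(f[1L],
                split_metabolites(f[2L], ln),
                split_metabolites(f[3L], ln),
                rev, cls)
}

match_reaction_class <- function(val, ln) {
  ok <- c("core_high", "core_moderate", "non_core", "unlabeled")
  if (!val %in% ok)
    stop("line ", ln, ": unknown reaction class '", val, "'")
  val
}

split_metabolites <- function(side, ln) {
  toks <- trimws(strsplit(side, "[+,]")[[1L]])
  toks <- toks[toks != ""]
  if (length(toks) == 0L)
    stop("line ", ln, ": empty side of reaction")
  for (tok in toks) {
    if (!grepl("^[^][]+\\[[^][]+\\]$", tok))
      stop("line ", ln, ": malformed metabolite token '", tok,
           "' (expected name[compartment])")
  }
  unique(toks)
}

make_reaction <- function(id, substrates, products, reversible, cls) {
  structure(
    list(id = id,
         substrates = substrates,
         products = products,
         reversible = reversible,
         reaction_class = cls,
         is_transport = length(unique(met_compartment(
           c(substrates, products)))) >= 2L),
    class = "reaction")
}

#' Compartment and base name of metabolite ids
#'
#' @param ids Character vector of `name[compartment]` metabolite ids.
#' @return Character vector of compartment codes (or base names).
#' @export
met_compartment <- function(ids) {
  sub("^.*\\[([^][]+)\\]$", "\\1", ids)
}

#' @rdname met_compartment
#' @export
met_base <- function(ids) {
  sub("\\[[^][]+\\]$", "", ids)
}

#' Serialize reactions back to the arrow dialect
#'
#' Inverse of [parse_reactions()] up to whitespace: re-parsing the output
#' yields an identical reaction set and network.
#'
#' @param reactions A `reaction_set`.
#' @return Character vector, one record per reaction.
#' @export
format_reactions <- function(reactions) {
  vapply(reactions, function(r) {
    arrow <- if (r$reversible) "<->" else "->"
    line <- paste0(r$id, ": ",
                   paste(r$substrates, collapse = " + "), " ", arrow, " ",
                   paste(r$products, collapse = " + "))
    if (r$reaction_class != "unlabeled")
      line <- paste0(line, " ; class=", r$reaction_class)
    if (r$reversible) line <- paste0(line, " ; rev=1")
    line
  }, character(1))
}

#' @rdname format_reactions
#' @param path Output file path.
#' @export
write_reactions <- function(reactions, path) {
  writeLines(format_reactions(reactions), path)
  invisible(path)
}

#' @export
print.reaction_set <- function(x, ...) {
  n_tr <- sum(vapply(x, `[[`, logical(1), "is_transport"))
  cat("Reaction set:", length(x), "reactions (", n_tr, "transport )\n")
  invisible(x)
}
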