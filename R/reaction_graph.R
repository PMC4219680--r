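# Directed reaction dependency graph. A reaction u is upstream of r when
# some species is a product of u and a reactant of r; links mediated only by
# cofactor species are suppressed because ubiquitous carriers (ATP, NAD, H+,
# ...) would otherwise connect essentially everything to everything and
# fabricate pathways that share no carbon skeleton.

#' Expand a model's reactions into directed reactions
#'
#' Every irreversible reaction yields one directed reaction; every
#' reversible reaction yields two, the backward one carrying the suffix
#' `_rev` and mirrored reactant/product stoichiometry. Both directions share
#' the base reaction's rate information.
#'
#' @param model an `sbml_model` with all reversibility flags resolved (see
#'   [resolve_reversibility()]).
#' @return an object of class `directed_reactions`: a named list, each
#'   element a list with `id`, `base_id`, `reactants`, `products`,
#'   `modifiers`, `kinetic_constant`, `kinetic_math`.
#' @export
expand_directions <- function(model) {
  stopifnot(inherits(model, "sbml_model"))
  unset <- names(model$reactions)[vapply(model$reactions,
                                         function(r) is.na(r$reversible), TRUE)]
  if (length(unset))
    stop("unresolved reversibility for: ", paste(unset, collapse = ", "),
         "; run resolve_reversibility() first", call. = FALSE)
  out <- list()
  for (r in model$reactions) {
    fwd <- list(id = r$id, base_id = r$id, reactants = r$reactants,
                products = r$products, modifiers = r$modifiers,
                kinetic_constant = r$kinetic_constant,
                kinetic_math = r$kinetic_math)
    out[[r$id]] <- fwd
    if (isTRUE(r$reversible)) {
      rev_id <- paste0(r$id, "_rev")
      out[[rev_id]] <- list(id = rev_id, base_id = r$id,
                            reactants = r$products, products = r$reactants,
                            modifiers = r$modifiers,
                            kinetic_constant = r$kinetic_constant,
                            kinetic_math = r$kinetic_math)
    }
  }
  structure(out, class = "directed_reactions")
}

#' The built-in cofactor list
#'
#' Returns the set of ubiquitous carrier species excluded from reaction
#' graph edge formation: H+, AMP, ADP, ATP, CoA, NAD, NADH, NADP, NADPH and
#' phosphate. Because genome-scale models use compartment-suffixed ids
#' (e.g. `M_atp_c`), an alias table maps these canonical names onto the
#' model's id convention; names with no alias are kept verbatim.
#'
#' @param extra character vector of additional species names/ids to include.
#' @param include_default if `FALSE`, only `extra` is used.
#' @param aliases named character vector (canonical name or user alias ->
#'   model species id), e.g. from [read_alias_table()].
#' @return character vector of species ids treated as cofactors.
#' @export
default_cofactors <- function(extra = character(), include_default = TRUE,
                              aliases = NULL) {
  base <- if (include_default)
    c("H", "AMP", "ADP", "ATP", "CoA", "NAD", "NADH", "NADP", "NADPH",
      "phosphate")
  else character()
  out <- unique(c(base, extra))
  if (!is.null(aliases) && length(aliases)) {
    hit <- match(out, names(aliases))
    out[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
    out <- unique(out)
  }
  out
}

#' Read a cofactor list file
#'
#' One species name or id per line; `#` starts a comment; blank lines are
#' ignored.
#'
#' @param path file path.
#' @return character vector.
#' @export
read_cofactor_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Read a two-column alias table (alias TAB model-id)
#' @param path file path.
#' @return named character vector mapping alias -> model species id.
#' @export
read_alias_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(), character()))
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("alias table line not of the form 'alias<TAB>model-id': ",
         lines[bad][1L], call. = FALSE)
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

#' Build the reaction dependency graph
#'
#' An edge `u -> r` exists iff some species that is not a cofactor is a
#' product of `u` and a reactant of `r`. The two directions of one
#' reversible base reaction are never connected to each other (the link
#' would be a trivial two-cycle carrying no pathway information), edges are
#' duplicate-free, and modifier species create no edges.
#'
#' @param directed a `directed_reactions` object from [expand_directions()].
#' @param cofactors character vector of species ids excluded from edge
#'   formation (see [default_cofactors()]).
#' @return an object of class `reaction_graph` with elements `nodes` (the
#'   directed reactions), `upstream` and `downstream` (named lists of
#'   character vectors), and `cofactors`.
#' @export
build_graph <- function(directed, cofactors = default_cofactors()) {
  stopifnot(inherits(directed, "directed_reactions"))
  ids <- names(directed)
  upstream <- stats::setNames(vector("list", length(ids)), ids)
  downstream <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    upstream[[id]] <- character()
    downstream[[id]] <- character()
  }
  # species -> producing / consuming directed reactions (cofactors excluded)
  producers <- list()
  consumers <- list()
  for (id in ids) {
    node <- directed[[id]]
    for (s in setdiff(names(node$products), cofactors))
      producers[[s]] <- c(producers[[s]], id)
    for (s in setdiff(names(node$reactants), cofactors))
      consumers[[s]] <- c(consumers[[s]], id)
  }
  for (s in intersect(names(producers), names(consumers))) {
    for (u in producers[[s]]) {
      for (r in consumers[[s]]) {
        if (directed[[u]]$base_id == directed[[r]]$base_id) next
        if (!r %in% downstream[[u]]) {
          downstream[[u]] <- c(downstream[[u]], r)
          upstream[[r]] <- c(upstream[[r]], u)
        }
      }
    }
  }
  # deterministic ordering regardless of species iteration order
  upstream <- lapply(upstream, sort)
  downstream <- lapply(downstream, sort)
  structure(list(nodes = directed, upstream = upstream,
                 downstream = downstream, cofactors = cofactors),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$downstream))
  cat("reaction graph:", length(x$nodes), "directed reactions,",
      n_edges, "edges,", length(x$cofactors), "cofactors excluded\n")
  invisible(x)
}

#' Write the graph's edge list to a text file
#'
#' One edge per line, `upstream_id<TAB>downstream_id`.
#'
#' @param graph a `reaction_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "reaction_graph"))
  lines <- character()
  for (u in names(graph$downstream))
    for (d in graph$downstream[[u]])
      lines <- c(lines, paste(u, d, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
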