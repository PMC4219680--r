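# Model slicing: enumerate the reaction paths that can create a sink
# species (pathway candidates), take the union of their reactions, and add
# the first-degree downstream consumers of the species on those paths. The
# result is the sub-model that has a dynamic influence on the sink.

#' Enumerate pathway candidates for a sink species
#'
#' Walks the reaction graph upstream from every reaction that produces the
#' sink, depth-first with a per-path visited set (so a directed reaction
#' never repeats within one candidate and cycles terminate). A path becomes
#' a candidate at a root: a reaction with no unvisited upstream neighbours,
#' or — when a `source` is given — a reaction all of whose reactants are
#' already accounted for (the source itself, a cofactor, or a boundary
#' species). With a `source`, only candidates rooted at such reactions are
#' retained; candidates whose reaction set duplicates another's are dropped.
#'
#' @param graph a `reaction_graph`.
#' @param sink species id whose production the slice targets.
#' @param source optional species id to which candidate roots are
#'   constrained.
#' @param boundary character vector of boundary species ids (allowed as
#'   root reactants besides the source and the cofactors).
#' @param species optional character vector of known species ids beyond
#'   those appearing in graph reactions (a sink that exists in the model
#'   but touches no reaction is unreachable, not unknown).
#' @param max_candidates safety cap on the enumeration (default 1e6).
#' @return list of candidates; each is a list with `reactions` (directed
#'   reaction ids ordered root -> sink producer) and `root_reactants` (the
#'   non-cofactor species consumed at the root).
#' @export
enumerate_candidates <- function(graph, sink, source = NULL,
                                 boundary = character(),
                                 species = character(),
                                 max_candidates = 1e6) {
  stopifnot(inherits(graph, "reaction_graph"))
  universe <- unique(c(unlist(lapply(graph$nodes, function(n)
    c(names(n$reactants), names(n$products)))), species, boundary))
  if (!sink %in% universe)
    stop("unknown sink species: ", sink, call. = FALSE)
  if (!is.null(source) && !source %in% universe)
    stop("unknown source species: ", source, call. = FALSE)

  allowed_roots <- c(source, graph$cofactors, boundary)
  root_ok <- function(id) {
    !is.null(source) &&
      all(names(graph$nodes[[id]]$reactants) %in% allowed_roots)
  }

  producers <- names(graph$nodes)[vapply(graph$nodes, function(n)
    sink %in% names(n$products), TRUE)]
  out <- new.env(parent = emptyenv())
  out$paths <- vector("list", 64L)
  out$n <- 0L
  emit <- function(path) {
    if (out$n >= max_candidates)
      stop("candidate enumeration exceeded max_candidates = ",
           max_candidates, call. = FALSE)
    out$n <- out$n + 1L
    if (out$n > length(out$paths))
      out$paths <- c(out$paths, vector("list", length(out$paths)))
    out$paths[[out$n]] <- path
  }
  walk <- function(head, path) {
    ups <- setdiff(graph$upstream[[head]], path)
    if (!length(ups)) {
      emit(path)
      return(invisible())
    }
    if (root_ok(head)) emit(path)
    for (u in sort(ups)) walk(u, c(u, path))
  }
  for (p in sort(producers)) walk(p, p)
  paths <- out$paths[seq_len(out$n)]

  if (!is.null(source)) paths <- Filter(function(p) root_ok(p[[1L]]), paths)
  # duplicate sequences, then completely redundant candidates (equal sets)
  if (length(paths)) {
    keys <- vapply(paths, paste, "", collapse = ">")
    paths <- paths[!duplicated(keys)]
    setkeys <- vapply(paths, function(p) paste(sort(unique(p)), collapse = "|"),
                      "")
    paths <- paths[!duplicated(setkeys)]
  }
  lapply(paths, function(p) {
    list(reactions = p,
         root_reactants = setdiff(names(graph$nodes[[p[[1L]]]]$reactants),
                                  graph$cofactors))
  })
}

#' Slice a model relative to a sink species
#'
#' The slice's reactions are the unique base reactions of all pathway
#' candidates, plus every first-degree downstream reaction that consumes a
#' species lying on a candidate (those consumers compete for the sink's
#' precursors and so influence its trajectory); species introduced only by
#' that expansion do not recurse further, and cofactor species never
#' qualify a reaction for the expansion. The slice's species are all
#' reactants and products of the slice's reactions.
#'
#' @inheritParams enumerate_candidates
#' @param model the parent `sbml_model`.
#' @param state optional named amounts vector; when given, candidates whose
#'   root reaction has zero propensity in that state are dropped
#'   (state-dependent slicing).
#' @return an object of class `model_slice`: `sink`, `source`, `reactions`
#'   (base ids), `species`, `candidates`, `parent`.
#' @export
slice_model <- function(model, graph, sink, source = NULL, state = NULL) {
  stopifnot(inherits(model, "sbml_model"), inherits(graph, "reaction_graph"))
  if (!sink %in% model$species$id)
    stop("unknown sink species: ", sink, call. = FALSE)
  boundary <- model$species$id[model$species$boundary]
  cands <- enumerate_candidates(graph, sink, source, boundary,
                                species = model$species$id)
  if (!is.null(state)) {
    st <- list(amounts = state, params = model$parameters,
               compartments = model$compartments)
    cands <- Filter(function(cand) {
      propensity(graph$nodes[[cand$reactions[[1L]]]], st) > 0
    }, cands)
  }
  if (!length(cands))
    stop("empty slice: sink unreachable from source", call. = FALSE)

  cand_ids <- unique(unlist(lapply(cands, `[[`, "reactions")))
  base_ids <- unique(vapply(cand_ids, function(id) graph$nodes[[id]]$base_id,
                            ""))
  cand_species <- unique(c(sink, unlist(lapply(cand_ids, function(id) {
    n <- graph$nodes[[id]]
    c(names(n$reactants), names(n$products))
  }))))
  # first-degree downstream expansion: consumers of candidate species;
  # no recursion from species that only this expansion introduces
  expand_species <- setdiff(cand_species, graph$cofactors)
  extra <- character()
  for (id in names(graph$nodes)) {
    n <- graph$nodes[[id]]
    if (n$base_id %in% base_ids) next
    if (any(names(n$reactants) %in% expand_species))
      extra <- c(extra, n$base_id)
  }
  slice_reactions <- sort(unique(c(base_ids, extra)))
  slice_species <- sort(unique(c(sink, unlist(lapply(
    model$reactions[slice_reactions], function(r)
      c(names(r$reactants), names(r$products), r$modifiers))))))
  structure(list(sink = sink, source = source,
                 reactions = slice_reactions, species = slice_species,
                 candidates = cands, parent = model),
            class = "model_slice")
}

#' @export
print.model_slice <- function(x, ...) {
  cat("model slice for sink", x$sink,
      if (!is.null(x$source)) paste("(source", x$source, ")") else "", "\n")
  cat(" ", length(x$candidates), "pathway candidates;",
      length(x$reactions), "reactions;", length(x$species), "species\n")
  invisible(x)
}

#' Complexity report for a slice
#'
#' Model reaction count is the complexity measure; the percent reduction is
#' `100 * (1 - slice reactions / parent reactions)`.
#'
#' @param parent the parent `sbml_model`.
#' @param slice a `model_slice` built from it.
#' @return list with parent/slice reaction and species counts,
#'   `n_candidates` and `pct_reduction`.
#' @export
complexity_report <- function(parent, slice) {
  stopifnot(inherits(parent, "sbml_model"), inherits(slice, "model_slice"))
  list(parent_reactions = length(parent$reactions),
       parent_species = nrow(parent$species),
       slice_reactions = length(slice$reactions),
       slice_species = length(slice$species),
       n_candidates = length(slice$candidates),
       pct_reduction = 100 * (1 - length(slice$reactions) /
                                length(parent$reactions)))
}

#' Report expected graph edges that are absent
#'
#' Diagnostic for missing connectivity: each expected (upstream,
#' downstream) base-reaction pair with no corresponding edge between any of
#' their directions is returned. A pair expected on biochemical grounds but
#' absent from the graph typically points at a wrong reversibility flag or
#' an over-eager cofactor entry.
#'
#' @param graph a `reaction_graph`.
#' @param expected_pairs data.frame or 2-column matrix/list of
#'   (upstream base id, downstream base id) pairs.
#' @return data.frame of the absent pairs (0 rows when all are present).
#' @export
missing_link_report <- function(graph, expected_pairs) {
  stopifnot(inherits(graph, "reaction_graph"))
  ep <- as.data.frame(expected_pairs, stringsAsFactors = FALSE)
  if (ncol(ep) != 2L) stop("expected_pairs must have two columns")
  names(ep) <- c("upstream", "downstream")
  base_ids <- vapply(graph$nodes, `[[`, "", "base_id")
  absent <- logical(nrow(ep))
  for (i in seq_len(nrow(ep))) {
    us <- names(base_ids)[base_ids == ep$upstream[i]]
    ds <- names(base_ids)[base_ids == ep$downstream[i]]
    found <- FALSE
    for (u in us)
      if (any(ds %in% graph$downstream[[u]])) { found <- TRUE; break }
    absent[i] <- !found
  }
  ep[absent, , drop = FALSE]
}
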