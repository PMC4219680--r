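# Independent oracles and small builders used across the suite. These are
# deliberately written as naive brute force, separate from the package's
# algorithms, so the two routes can disagree.

# All graph edges by triple loop over (producer, consumer, species).
brute_edges <- function(directed, cofactors) {
  edges <- character()
  ids <- names(directed)
  for (u in ids) for (r in ids) {
    if (directed[[u]]$base_id == directed[[r]]$base_id) next
    shared <- intersect(names(directed[[u]]$products),
                        names(directed[[r]]$reactants))
    if (length(setdiff(shared, cofactors)))
      edges <- c(edges, paste(u, r, sep = "->"))
  }
  sort(unique(edges))
}

graph_edges <- function(graph) {
  edges <- character()
  for (u in names(graph$downstream))
    for (d in graph$downstream[[u]])
      edges <- c(edges, paste(u, d, sep = "->"))
  sort(unique(edges))
}

# All simple paths ending at a sink producer whose first reaction has no
# upstream neighbour outside the path; forward DFS from every node.
brute_candidates <- function(graph, sink) {
  producers <- names(graph$nodes)[vapply(graph$nodes, function(n)
    sink %in% names(n$products), TRUE)]
  paths <- list()
  grow <- function(path) {
    head_node <- path[length(path)]
    if (head_node %in% producers &&
        !length(setdiff(graph$upstream[[path[1L]]], path)))
      paths[[length(paths) + 1L]] <<- path
    for (d in graph$downstream[[head_node]])
      if (!d %in% path) grow(c(path, d))
  }
  for (start in names(graph$nodes)) grow(start)
  paths
}

# canonical comparison key: the collection of unique reaction sets
candidate_set_keys <- function(cands) {
  sort(unique(vapply(cands, function(p) {
    rx <- if (is.list(p)) p$reactions else p
    paste(sort(unique(rx)), collapse = "|")
  }, "")))
}

# replay an event log over a model's stoichiometry (boundary-aware)
replay_amounts <- function(model, events) {
  directed <- expand_directions(model)
  amounts <- stats::setNames(model$species$initial_amount, model$species$id)
  boundary <- stats::setNames(model$species$boundary, model$species$id)
  for (rid in events$reaction) {
    n <- directed[[rid]]
    for (s in names(n$reactants))
      if (!boundary[[s]]) amounts[[s]] <- amounts[[s]] - n$reactants[[s]]
    for (s in names(n$products))
      if (!boundary[[s]]) amounts[[s]] <- amounts[[s]] + n$products[[s]]
  }
  amounts
}

# hand-built trajectory for the metrics tests
synthetic_traj <- function(times, values, species = "X") {
  structure(list(times = times,
                 amounts = matrix(values, ncol = 1,
                                  dimnames = list(NULL, species)),
                 watch = species,
                 events = data.frame(step = integer(), time = numeric(),
                                     reaction = character()),
                 terminal = "COMPLETED", deadlock = NULL,
                 t_end = max(times)),
            class = "ssa_trajectory")
}

# a 2-species replenished selector: boundary reactant keeps both reactions
# available forever with constant weights
constant_weight_model <- function(k1, k2) {
  new_model(
    data.frame(id = c("A", "X", "Y"), name = c("A", "X", "Y"),
               compartment = "cell", initial_amount = c(1, 0, 0),
               boundary = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE),
    list(list(id = "R1", reactants = c(A = 1), products = c(X = 1),
              reversible = FALSE, kinetic_constant = k1),
         list(id = "R2", reactants = c(A = 1), products = c(Y = 1),
              reversible = FALSE, kinetic_constant = k2)))
}
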