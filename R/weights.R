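# Forward-algorithm-style predictive reaction weights: a probability-like
# score for reactions whose reactants are not yet available, aggregated
# from available upstream reactions. Weights are normalized to probability
# shares *before* any multiplication so that products can never exceed 1 —
# raw reaction weights do not obey probability axioms.

#' Predictive weights for all directed reactions
#'
#' Let `N(r) = a_r / a0` be the normalized reaction weight over currently
#' available reactions (0 when `a0 = 0`). Then
#' * if `a_r > 0`, the predictive weight is `alpha(r) = N(r)`;
#' * otherwise `alpha(r) = sum over upstream u of alpha(u) * beta(u -> r)`,
#'   where `beta(u -> r) = k_r / sum over downstream d of u of k_d` is the
#'   branch share of `r` among `u`'s competing downstream reactions,
#'   computed from kinetic constants (rate expressions are evaluated at
#'   unit amounts as a static proxy).
#'
#' Each node is evaluated once (memoized); nodes on the active recursion
#' stack contribute 0, so cycles terminate; all values are clamped to
#' `[0, 1]`.
#'
#' @param graph a `reaction_graph`.
#' @param state list with `amounts`, optionally `params`, `compartments`.
#' @param props optional precomputed [propensities()] result for the
#'   graph's nodes in `state`.
#' @return named numeric vector `alpha` over directed reaction ids, with
#'   attribute `"reaction_weight"` carrying the raw propensities.
#' @export
predictive_weights <- function(graph, state, props = NULL) {
  stopifnot(inherits(graph, "reaction_graph"))
  nodes <- graph$nodes
  ids <- sort(names(nodes))
  if (is.null(props)) props <- propensities(nodes, state)
  a <- props$a[ids]
  a0 <- props$a0
  N <- if (a0 > 0) a / a0 else stats::setNames(numeric(length(a)), ids)

  unit_state <- list(
    amounts = stats::setNames(
      rep(1, length(unique(unlist(lapply(nodes, function(n)
        c(names(n$reactants), names(n$products))))))),
      unique(unlist(lapply(nodes, function(n)
        c(names(n$reactants), names(n$products)))))),
    params = state$params, compartments = state$compartments)
  k_static <- vapply(ids, function(id) {
    n <- nodes[[id]]
    if (!is.null(n$kinetic_math)) {
      vals <- c(as.list(unit_state$amounts),
                as.list(state$params %||% numeric()),
                as.list(state$compartments %||% numeric()))
      eval_kinetic_math(n$kinetic_math, vals)
    } else if (!is.na(n$kinetic_constant)) n$kinetic_constant else 0
  }, 0)

  memo <- stats::setNames(rep(NA_real_, length(ids)), ids)
  on_stack <- stats::setNames(rep(FALSE, length(ids)), ids)
  alpha <- function(r) {
    if (!is.na(memo[[r]])) return(memo[[r]])
    if (on_stack[[r]]) return(0)
    if (a[[r]] > 0) {
      memo[[r]] <<- N[[r]]
      return(memo[[r]])
    }
    on_stack[[r]] <<- TRUE
    total <- 0
    for (u in graph$upstream[[r]]) {
      ks <- k_static[graph$downstream[[u]]]
      denom <- sum(ks)
      if (denom > 0)
        total <- total + alpha(u) * (k_static[[r]] / denom)
    }
    on_stack[[r]] <<- FALSE
    memo[[r]] <<- min(1, max(0, total))
    memo[[r]]
  }
  for (id in ids) alpha(id)
  structure(memo, reaction_weight = a)
}

#' Did a step produce a brand-new metabolite?
#'
#' True iff some species count went from 0 to positive between two states;
#' the debugger uses this as the trigger to recompute predictive weights
#' (recomputing on every firing is wasteful, and only a newly present
#' species can change reaction availability upstream of a blocked branch).
#'
#' @param prev,cur state lists (with `amounts`) from consecutive steps.
#' @return logical flag.
#' @export
on_new_metabolite <- function(prev, cur) {
  ids <- union(names(prev$amounts), names(cur$amounts))
  p <- prev$amounts[ids]; p[is.na(p)] <- 0
  q <- cur$amounts[ids]; q[is.na(q)] <- 0
  any(p == 0 & q > 0)
}
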