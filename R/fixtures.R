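# Synthetic model generators. Every algorithm in the package is testable on
# these without downloading anything; the topology definitions live here and
# only here, and fixtures are emitted as model documents (writable as SBML
# Level 3) rather than kept as files.

fixture_topologies <- c("CHAIN", "BRANCH", "CYCLE", "DIAMOND",
                        "FIG3A", "FIG3B", "FIG3C", "MINI_GLYCOLYSIS")

species_df <- function(ids, init = numeric(), boundary = character()) {
  amounts <- stats::setNames(numeric(length(ids)), ids)
  amounts[names(init)] <- init
  data.frame(id = ids, name = ids,
             compartment = "cell",
             initial_amount = as.numeric(amounts),
             boundary = ids %in% boundary,
             stringsAsFactors = FALSE)
}

rxn <- function(id, reactants, products, k, reversible = FALSE,
                modifiers = character()) {
  list(id = id, reactants = reactants, products = products,
       modifiers = modifiers, reversible = reversible, kinetic_constant = k)
}

#' Generate a synthetic test model
#'
#' Topologies:
#' * `CHAIN`: species `A1..An`, reactions `A1 -> A2`, ..., `A(n-1) -> An`.
#' * `BRANCH`: root `A` and children `B1..Bn`, one reaction per child.
#' * `CYCLE`: `A1 -> A2 -> ... -> An -> A1`.
#' * `DIAMOND`: `A -> B`, `A -> C`, `B -> S`, `C -> S` (two disjoint
#'   pathways into the sink `S`).
#' * `FIG3A`: pure upstream case `b -> a`; the slice for sink `a` keeps the
#'   whole model.
#' * `FIG3B`: `x -> a -> b -> c`; slicing for `a` keeps the first-degree
#'   downstream consumer (`a -> b`) and removes the second-degree one
#'   (`b -> c`).
#' * `FIG3C`: peer branch: `b -> a`, `b -> d`, `d -> e`; slicing for `a`
#'   keeps the peer consumer of `b` and removes the peer's own downstream.
#' * `MINI_GLYCOLYSIS`: a 10-reaction glycolysis-shaped chain with two
#'   ATP-consuming priming steps (hexokinase, phosphofructokinase) and two
#'   ATP-producing payoff steps, using the standard cofactors (ATP, ADP,
#'   NAD, NADH, phosphate, H). With no initial ATP the pathway cannot prime
#'   and deadlocks immediately; with a small ATP stake it shows the
#'   "ATP needed before ATP can be made" behavior. The cofactor ids used by
#'   the fixture are attached as `attr(model, "cofactors")`.
#'
#' @param topology one of `r paste(fixture_topologies, collapse = ", ")`.
#' @param n size parameter (chain/branch/cycle length), >= 2 where used.
#' @param k default rate constant for all reactions.
#' @param init named numeric vector overriding default initial amounts.
#' @return an `sbml_model` (deterministic given the arguments).
#' @export
make_fixture <- function(topology = c("CHAIN", "BRANCH", "CYCLE", "DIAMOND",
                                      "FIG3A", "FIG3B", "FIG3C",
                                      "MINI_GLYCOLYSIS"),
                         n = 3L, k = 1, init = numeric()) {
  topology <- match.arg(topology)
  m <- switch(topology,
    CHAIN = {
      stopifnot(n >= 2L)
      ids <- paste0("A", seq_len(n))
      rx <- lapply(seq_len(n - 1L), function(i)
        rxn(paste0("R", i), stats::setNames(1, ids[i]),
            stats::setNames(1, ids[i + 1L]), k))
      new_model(species_df(ids, c(A1 = 100)), rx)
    },
    BRANCH = {
      stopifnot(n >= 1L)
      ids <- c("A", paste0("B", seq_len(n)))
      rx <- lapply(seq_len(n), function(i)
        rxn(paste0("R", i), c(A = 1),
            stats::setNames(1, paste0("B", i)), k))
      new_model(species_df(ids, c(A = 100)), rx)
    },
    CYCLE = {
      stopifnot(n >= 2L)
      ids <- paste0("A", seq_len(n))
      rx <- lapply(seq_len(n), function(i)
        rxn(paste0("R", i), stats::setNames(1, ids[i]),
            stats::setNames(1, ids[if (i == n) 1L else i + 1L]), k))
      new_model(species_df(ids, c(A1 = 100)), rx)
    },
    DIAMOND = new_model(
      species_df(c("A", "B", "C", "S"), c(A = 100)),
      list(rxn("R1", c(A = 1), c(B = 1), k),
           rxn("R2", c(A = 1), c(C = 1), k),
           rxn("R3", c(B = 1), c(S = 1), k),
           rxn("R4", c(C = 1), c(S = 1), k))),
    FIG3A = new_model(
      species_df(c("a", "b"), c(b = 50)),
      list(rxn("R_ba", c(b = 1), c(a = 1), k))),
    FIG3B = new_model(
      species_df(c("x", "a", "b", "c"), c(x = 50)),
      list(rxn("R_xa", c(x = 1), c(a = 1), k),
           rxn("R_ab", c(a = 1), c(b = 1), k),
           rxn("R_bc", c(b = 1), c(c = 1), k))),
    FIG3C = new_model(
      species_df(c("a", "b", "d", "e"), c(b = 50)),
      list(rxn("R_ba", c(b = 1), c(a = 1), k),
           rxn("R_bd", c(b = 1), c(d = 1), k),
           rxn("R_de", c(d = 1), c(e = 1), k))),
    MINI_GLYCOLYSIS = {
      ids <- c("glc", "g6p", "f6p", "fbp", "g3p", "bpg", "pg3", "pg2",
               "pep", "pyr", "lac", "atp", "adp", "nad", "nadh", "pi", "h")
      defaults <- c(glc = 8, atp = 2, adp = 20, nad = 10, pi = 30)
      rx <- list(
        rxn("R_HEX",  c(glc = 1, atp = 1), c(g6p = 1, adp = 1, h = 1), k),
        rxn("R_PGI",  c(g6p = 1), c(f6p = 1), k),
        # payoff-committing step gets a higher default rate so a primed
        # hexose is carried through rather than priming spent twice up top
        rxn("R_PFK",  c(f6p = 1, atp = 1), c(fbp = 1, adp = 1), 10 * k),
        rxn("R_FBA",  c(fbp = 1), c(g3p = 2), k),
        rxn("R_GAPD", c(g3p = 1, nad = 1, pi = 1), c(bpg = 1, nadh = 1), k),
        rxn("R_PGK",  c(bpg = 1, adp = 1), c(pg3 = 1, atp = 1), k),
        rxn("R_PGM",  c(pg3 = 1), c(pg2 = 1), k),
        rxn("R_ENO",  c(pg2 = 1), c(pep = 1), k),
        rxn("R_PYK",  c(pep = 1, adp = 1), c(pyr = 1, atp = 1), k),
        rxn("R_LDH",  c(pyr = 1, nadh = 1), c(lac = 1, nad = 1), k))
      out <- new_model(species_df(ids, defaults), rx)
      attr(out, "cofactors") <- c("atp", "adp", "nad", "nadh", "pi", "h")
      out
    })
  if (length(init)) {
    idx <- match(names(init), m$species$id)
    if (anyNA(idx))
      stop("init names unknown species: ",
           paste(names(init)[is.na(idx)], collapse = ", "), call. = FALSE)
    m$species$initial_amount[idx] <- as.numeric(init)
  }
  for (id in names(m$reactions))
    if (is.na(m$reactions[[id]]$reversible))
      m$reactions[[id]]$reversible <- FALSE
  m$provenance <- list(path = paste0("<fixture:", topology, ">"),
                       level = "3", version = "1")
  m
}

#' Generate a random connected mass-action model
#'
#' A chain backbone over all species guarantees connectivity; additional
#' reactions draw 1-2 reactants and 1-2 products uniformly. Deterministic
#' given the seed; intended as the substrate for property tests and
#' brute-force oracles (sizes are capped at 100).
#'
#' @param n_species,n_reactions sizes (<= 100); `n_reactions` must be at
#'   least `n_species - 1` to fit the backbone.
#' @param seed integer seed.
#' @param p_reversible probability a non-backbone reaction is reversible.
#' @return an `sbml_model`.
#' @export
make_random_model <- function(n_species, n_reactions, seed,
                              p_reversible = 0) {
  stopifnot(n_species >= 1, n_species <= 100, n_reactions <= 100)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- paste0("S", seq_len(n_species))
  rx <- list()
  n_backbone <- min(n_reactions, max(0L, n_species - 1L))
  for (i in seq_len(n_backbone))
    rx[[i]] <- rxn(paste0("R", i), stats::setNames(1, ids[i]),
                   stats::setNames(1, ids[i + 1L]), k = 1)
  i <- length(rx)
  while (i < n_reactions) {
    i <- i + 1L
    nr <- sample(1:2, 1L)
    np <- sample(1:2, 1L)
    reac <- sample(ids, nr)
    prod <- sample(setdiff(ids, reac), min(np, n_species - nr))
    if (!length(prod)) prod <- sample(ids, 1L)
    rx[[i]] <- rxn(paste0("R", i),
                   stats::setNames(rep(1, length(reac)), reac),
                   stats::setNames(rep(1, length(prod)), prod),
                   k = 1, reversible = stats::runif(1) < p_reversible)
  }
  init <- stats::setNames(sample(0:50, n_species, replace = TRUE), ids)
  m <- new_model(species_df(ids, init), rx)
  m$provenance <- list(path = sprintf("<random:%d,%d,seed=%d>", n_species,
                                      n_reactions, seed),
                       level = "3", version = "1")
  m
}
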