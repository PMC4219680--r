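# Pathway-candidate enumeration and model slicing.

chain_graph <- function(n, k = 1) {
  m <- make_fixture("CHAIN", n = n, k = k)
  list(model = m,
       graph = build_graph(expand_directions(m), cofactors = character()))
}

test_that("base cases: single producing reaction and the diamond", {
  cg <- chain_graph(2)                       # A1 -> A2 only
  cands <- enumerate_candidates(cg$graph, "A2")
  expect_length(cands, 1L)
  expect_identical(cands[[1L]]$reactions, "R1")
  expect_identical(cands[[1L]]$root_reactants, "A1")

  m <- make_fixture("DIAMOND")
  g <- build_graph(expand_directions(m), cofactors = character())
  cands <- enumerate_candidates(g, "S")
  expect_length(cands, 2L)
  expect_setequal(candidate_set_keys(cands), c("R1|R3", "R2|R4"))

  expect_error(enumerate_candidates(g, "nope"), "unknown sink")
})

test_that("upstream-chain slicing keeps the whole model", {
  m <- make_fixture("FIG3A")
  g <- build_graph(expand_directions(m), cofactors = character())
  sl <- slice_model(m, g, "a")
  expect_setequal(sl$reactions, names(m$reactions))
  expect_setequal(sl$species, m$species$id)
})

test_that("first-degree downstream consumers are kept, second-degree removed", {
  m <- make_fixture("FIG3B")                 # x -> a -> b -> c
  g <- build_graph(expand_directions(m), cofactors = character())
  sl <- slice_model(m, g, "a")
  expect_setequal(sl$reactions, c("R_xa", "R_ab"))
  expect_false("R_bc" %in% sl$reactions)
  expect_setequal(sl$species, c("x", "a", "b"))
})

test_that("peer-branch consumers are kept but their downstream is cleaved", {
  m <- make_fixture("FIG3C")                 # b -> a, b -> d, d -> e
  g <- build_graph(expand_directions(m), cofactors = character())
  sl <- slice_model(m, g, "a")
  expect_setequal(sl$reactions, c("R_ba", "R_bd"))
  expect_false("R_de" %in% sl$reactions)
  expect_setequal(sl$species, c("a", "b", "d"))
})

test_that("candidates match the brute-force simple-path oracle on random models", {
  for (seed in 1:8) {
    m <- make_random_model(7, 11, seed = seed)
    m <- resolve_reversibility(m)$model
    g <- build_graph(expand_directions(m), cofactors = character())
    sink <- paste0("S", 1 + seed %% 7)
    cands <- tryCatch(enumerate_candidates(g, sink),
                      error = function(e) list())
    expect_identical(candidate_set_keys(cands),
                     candidate_set_keys(brute_candidates(g, sink)))
  }
})

test_that("slices are subsets of the parent and slicing is idempotent", {
  for (seed in c(3, 9, 27)) {
    m <- make_random_model(9, 14, seed = seed)
    m <- resolve_reversibility(m)$model
    g <- build_graph(expand_directions(m), cofactors = character())
    sl <- tryCatch(slice_model(m, g, "S5"), error = function(e) NULL)
    if (is.null(sl)) next
    expect_true(all(sl$reactions %in% names(m$reactions)))
    expect_true(all(sl$species %in% m$species$id))
    doc <- export_slice(sl)
    g2 <- build_graph(expand_directions(doc), cofactors = character())
    sl2 <- slice_model(doc, g2, "S5")
    expect_setequal(sl2$reactions, sl$reactions)
  }
})

test_that("a source constraint never enlarges the candidate set", {
  m <- make_fixture("MINI_GLYCOLYSIS")
  cof <- attr(m, "cofactors")
  g <- build_graph(expand_directions(m), cofactors = cof)
  free <- enumerate_candidates(g, "pyr")
  sourced <- enumerate_candidates(g, "pyr", source = "glc")
  expect_true(length(sourced) <= length(free))
  expect_gt(length(sourced), 0L)
  for (cand in sourced)
    expect_true(all(cand$root_reactants %in% "glc"))

  # diamond with source = B keeps only the branch rooted at B's consumer
  md <- make_fixture("DIAMOND")
  gd <- build_graph(expand_directions(md), cofactors = character())
  expect_length(enumerate_candidates(gd, "S", source = "B"), 1L)
  expect_length(enumerate_candidates(gd, "S", source = "A"), 2L)
})

test_that("cofactor-only consumers never trigger downstream expansion", {
  # R_c consumes only the cofactor product of the candidate path, so it
  # stays out of the slice even though it touches a candidate species
  sp <- data.frame(id = c("A", "B", "ATP", "W"),
                   name = c("A", "B", "ATP", "W"), compartment = "cell",
                   initial_amount = c(10, 0, 0, 5), boundary = FALSE,
                   stringsAsFactors = FALSE)
  rx <- list(list(id = "R_ab", reactants = c(A = 1),
                  products = c(B = 1, ATP = 1), reversible = FALSE,
                  kinetic_constant = 1),
             list(id = "R_c", reactants = c(ATP = 1, W = 1),
                  products = c(W = 1), reversible = FALSE,
                  kinetic_constant = 1))
  m <- new_model(sp, rx)
  g <- build_graph(expand_directions(m), cofactors = "ATP")
  sl <- slice_model(m, g, "B")
  expect_identical(sl$reactions, "R_ab")
})

test_that("state-dependent slicing drops candidates with unavailable roots", {
  m <- make_fixture("DIAMOND")
  g <- build_graph(expand_directions(m), cofactors = character())
  # with A present both branches alive; with nothing present no slice
  sl <- slice_model(m, g, "S", state = c(A = 10, B = 0, C = 0, S = 0))
  expect_setequal(sl$reactions, c("R1", "R2", "R3", "R4"))
  expect_error(slice_model(m, g, "S", state = c(A = 0, B = 0, C = 0, S = 0)),
               "sink unreachable")
})

test_that("complexity report arithmetic", {
  cg <- chain_graph(11)                      # 10 reactions
  sl <- slice_model(cg$model, cg$graph, "A5")  # keeps R1..R4 + consumer R5
  rep <- complexity_report(cg$model, sl)
  expect_equal(rep$parent_reactions, 10L)
  expect_equal(rep$slice_reactions, 5L)
  expect_equal(rep$pct_reduction, 50)
  # slice = parent gives 0%
  sl_all <- slice_model(cg$model, cg$graph, "A11")
  expect_equal(complexity_report(cg$model, sl_all)$pct_reduction, 0)
})

test_that("missing_link_report diagnoses a wrong reversibility flag", {
  # R_PGM encoded backwards and irreversible: pg2 -> pg3; the expected
  # upstream link into R_ENO (pg2 -> pep) then cannot exist
  sp <- data.frame(id = c("pg3", "pg2", "pep"),
                   name = c("pg3", "pg2", "pep"), compartment = "cell",
                   initial_amount = c(10, 0, 0), boundary = FALSE,
                   stringsAsFactors = FALSE)
  rx <- list(list(id = "R_PGM", reactants = c(pg2 = 1), products = c(pg3 = 1),
                  reversible = FALSE, kinetic_constant = 1),
             list(id = "R_ENO", reactants = c(pg2 = 1), products = c(pep = 1),
                  reversible = FALSE, kinetic_constant = 1))
  m <- new_model(sp, rx)
  g_bad <- build_graph(expand_directions(m), cofactors = character())
  expected <- data.frame(upstream = "R_PGM", downstream = "R_ENO")
  rep_bad <- missing_link_report(g_bad, expected)
  expect_equal(nrow(rep_bad), 1L)

  m_fix <- resolve_reversibility(m, overrides = c(R_PGM = TRUE))$model
  g_fix <- build_graph(expand_directions(m_fix), cofactors = character())
  expect_equal(nrow(missing_link_report(g_fix, expected)), 0L)

  # two absent of three expected
  expected3 <- data.frame(upstream = c("R_PGM", "R_ENO", "R_ENO"),
                          downstream = c("R_ENO", "R_PGM", "R_ENO"))
  expect_equal(nrow(missing_link_report(g_bad, expected3)), 3L)
  expect_equal(nrow(missing_link_report(g_fix, expected3)), 2L)
})
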