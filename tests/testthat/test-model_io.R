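# SBML reading, writing, repair and merge.

test_that("fixture models round-trip through SBML write and read", {
  for (topo in c("CHAIN", "DIAMOND", "CYCLE", "FIG3B", "MINI_GLYCOLYSIS")) {
    m <- make_fixture(topo)
    f <- withr::local_tempfile(fileext = ".xml")
    write_model(m, f)
    m2 <- load_model(f)
    expect_identical(m2$species$id, m$species$id)
    expect_equal(m2$species$initial_amount, m$species$initial_amount)
    expect_identical(names(m2$reactions), names(m$reactions))
    for (id in names(m$reactions)) {
      expect_equal(m2$reactions[[id]]$reactants, m$reactions[[id]]$reactants)
      expect_equal(m2$reactions[[id]]$products, m$reactions[[id]]$products)
      expect_identical(m2$reactions[[id]]$reversible,
                       m$reactions[[id]]$reversible)
      expect_equal(m2$reactions[[id]]$kinetic_constant,
                   m$reactions[[id]]$kinetic_constant)
    }
  }
})

test_that("kinetic-law expressions survive a round trip and evaluate", {
  m <- make_fixture("CHAIN", n = 3)
  m$reactions[["R1"]]$kinetic_constant <- NA_real_
  m$reactions[["R1"]]$kinetic_math <- quote(0.5 * A1)
  f <- withr::local_tempfile(fileext = ".xml")
  write_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$reactions[["R1"]]$kinetic_math, quote(0.5 * A1))
  st <- list(amounts = c(A1 = 10, A2 = 0, A3 = 0))
  expect_equal(propensity(expand_directions(m2)[["R1"]], st), 5)
})

test_that("loader reports unset reversibility, missing amounts and missing kinetics", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="m">',
    '    <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="A" compartment="cell" initialAmount="10"/>',
    '      <species id="B" compartment="cell"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="R_PGM">',
    '        <listOfReactants><speciesReference species="A"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="B"/></listOfProducts>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  warns <- capture_warnings(m <- load_model(f))
  expect_true(any(grepl("WARN REVERSIBLE_UNSET R_PGM", warns)))
  expect_true(any(grepl("WARN AMOUNT_MISSING B", warns)))
  expect_true(any(grepl("WARN KINETICS_MISSING R_PGM", warns)))
  expect_true(is.na(m$reactions[["R_PGM"]]$reversible))
  expect_equal(m$species$initial_amount[m$species$id == "B"], 0)
  # default stoichiometry of a bare speciesReference is 1
  expect_equal(m$reactions[["R_PGM"]]$reactants, c(A = 1))

  res <- resolve_reversibility(m, default = TRUE)
  expect_identical(res$changed, "R_PGM")
  expect_true(res$model$reactions[["R_PGM"]]$reversible)
  # idempotent: second pass changes nothing
  res2 <- resolve_reversibility(res$model, default = TRUE)
  expect_identical(res2$changed, character())
  expect_identical(res2$model, res$model)
})

test_that("resolve_reversibility applies overrides and validates ids", {
  m <- make_fixture("CHAIN", n = 3)   # fixtures are fully irreversible
  res <- resolve_reversibility(m, overrides = c(R1 = TRUE))
  expect_identical(res$changed, "R1")
  expect_true(res$model$reactions[["R1"]]$reversible)
  res_back <- resolve_reversibility(res$model, overrides = c(R1 = FALSE))
  expect_identical(res_back$changed, "R1")
  expect_false(res_back$model$reactions[["R1"]]$reversible)
  expect_error(resolve_reversibility(m, overrides = c(R_X = TRUE)), "R_X")
  # no unset flags, any default: unchanged
  expect_identical(resolve_reversibility(m, default = FALSE)$changed,
                   character())
})

test_that("assign_default_kinetics fills only the gaps", {
  m <- make_fixture("CHAIN", n = 4)   # R1..R3 all carry constants
  m$reactions[["R1"]]$kinetic_constant <- NA_real_
  m$reactions[["R1"]]$kinetic_math <- quote(2 * A1)   # has math: untouched
  m$reactions[["R2"]]$kinetic_constant <- NA_real_
  m$reactions[["R3"]]$kinetic_constant <- NA_real_
  m2 <- assign_default_kinetics(m, k = 2)
  expect_setequal(attr(m2, "changed"), c("R2", "R3"))
  expect_equal(m2$reactions[["R2"]]$kinetic_constant, 2)
  expect_null(m2$reactions[["R2"]]$kinetic_math)
  expect_true(is.na(m2$reactions[["R1"]]$kinetic_constant))
  # all reactions already carry kinetics: no-op
  m3 <- assign_default_kinetics(m2, k = 5)
  expect_identical(attr(m3, "changed"), character())
})

test_that("export_slice contains exactly the slice and merge round-trips", {
  m <- make_fixture("CHAIN", n = 3)
  g <- build_graph(expand_directions(m), cofactors = character())
  sl <- slice_model(m, g, "A3")
  doc <- export_slice(sl)
  expect_setequal(names(doc$reactions), sl$reactions)
  expect_setequal(doc$species$id, sl$species)
  expect_equal(length(doc$reactions), 2L)

  # unedited merge leaves the original untouched
  merged <- merge_slice(m, doc)
  expect_identical(merged$changed, character())
  expect_identical(names(merged$model$reactions), names(m$reactions))

  # an edited rate constant propagates, everything else untouched
  doc$reactions[["R1"]]$kinetic_constant <- 9
  merged2 <- merge_slice(m, doc)
  expect_identical(merged2$changed, "R1")
  expect_equal(merged2$model$reactions[["R1"]]$kinetic_constant, 9)
  expect_equal(merged2$model$reactions[["R2"]]$kinetic_constant,
               m$reactions[["R2"]]$kinetic_constant)

  # merge then re-slice returns the edited slice (up to order)
  g2 <- build_graph(expand_directions(merged2$model), cofactors = character())
  sl2 <- slice_model(merged2$model, g2, "A3")
  expect_setequal(sl2$reactions, sl$reactions)
  expect_equal(export_slice(sl2)$reactions[["R1"]]$kinetic_constant, 9)
})

test_that("merge_slice appends new ids and rejects id-type clashes", {
  m <- make_fixture("CHAIN", n = 3)
  extra <- make_fixture("CHAIN", n = 3)
  extra$species <- rbind(extra$species,
                         data.frame(id = "Znew", name = "Znew",
                                    compartment = "cell",
                                    initial_amount = 7, boundary = FALSE))
  extra$reactions[["Rnew"]] <- list(id = "Rnew", name = "Rnew",
                                    reactants = c(A3 = 1),
                                    products = c(Znew = 1),
                                    modifiers = character(),
                                    reversible = FALSE,
                                    kinetic_constant = 1,
                                    kinetic_math = NULL)
  merged <- merge_slice(m, extra)
  expect_setequal(merged$changed, c("Znew", "Rnew"))
  expect_true("Znew" %in% merged$model$species$id)
  expect_true("Rnew" %in% names(merged$model$reactions))

  clash <- make_fixture("CHAIN", n = 3)
  clash$species$id[1] <- "R1"   # species id reusing a reaction id
  clash$species$name[1] <- "R1"
  expect_error(merge_slice(m, clash), "both species and reaction")
})

test_that("non-integer stoichiometries are rounded up with a warning", {
  sp <- data.frame(id = c("A", "B"), name = c("A", "B"),
                   compartment = "cell", initial_amount = c(10, 0),
                   boundary = FALSE, stringsAsFactors = FALSE)
  expect_warning(
    m <- new_model(sp, list(list(id = "R1", reactants = c(A = 1.5),
                                 products = c(B = 1), reversible = FALSE,
                                 kinetic_constant = 1))),
    "STOICH_ROUNDED")
  expect_equal(m$reactions[["R1"]]$reactants, c(A = 2))
})

test_that("load_model fails informatively on bad input", {
  expect_error(load_model(file.path(tempdir(), "nope.xml")), "cannot read")
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<notsbml/>", f)
  expect_error(load_model(f), "expected <sbml>")
})
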