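# SBML input/output and model-document manipulation. Every SBML dialect
# decision (reversibility defaults, stoichiometry rounding, missing amounts)
# lives in this file; the rest of the package only sees `sbml_model` objects.

.warn_repair <- function(code, id, msg) {
  warning(sprintf("WARN %s %s %s", code, id, msg), call. = FALSE)
}

#' Construct a model document
#'
#' In-memory representation of an SBML model: a species table, a named list
#' of reactions, global parameters and compartments. This is the container
#' every other module consumes; [load_model()] and the fixture generators
#' both produce it.
#'
#' @param species data.frame with columns `id`, `name`, `compartment`,
#'   `initial_amount`, `boundary`.
#' @param reactions named list; each element a list with `id`, `name`,
#'   `reactants` (named numeric, species id -> integer stoichiometry),
#'   `products` (same shape), `modifiers` (character), `reversible`
#'   (TRUE/FALSE/NA; NA means the source file left it unset),
#'   `kinetic_constant` (numeric or NA) and `kinetic_math`
#'   (R language object or NULL).
#' @param parameters named numeric vector of global parameters.
#' @param compartments named numeric vector of compartment sizes.
#' @param provenance list with `path`, `level`, `version` (may be empty).
#' @return an object of class `sbml_model`.
#' @export
new_model <- function(species, reactions, parameters = numeric(),
                      compartments = c(cell = 1), provenance = list()) {
  stopifnot(is.data.frame(species),
            all(c("id", "name", "compartment", "initial_amount",
                  "boundary") %in% names(species)))
  if (anyDuplicated(species$id))
    stop("duplicate species id: ",
         species$id[duplicated(species$id)][1L], call. = FALSE)
  if (any(species$initial_amount < 0, na.rm = TRUE))
    stop("negative initial amount", call. = FALSE)
  reactions <- lapply(reactions, normalize_reaction, species_ids = species$id)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(names(reactions)))
    stop("duplicate reaction id: ",
         names(reactions)[duplicated(names(reactions))][1L], call. = FALSE)
  structure(list(species = species, reactions = reactions,
                 parameters = parameters, compartments = compartments,
                 provenance = provenance),
            class = "sbml_model")
}

normalize_reaction <- function(r, species_ids) {
  stopifnot(!is.null(r$id))
  r$name <- r$name %||% r$id
  r$reactants <- normalize_stoich(r$reactants, r$id)
  r$products <- normalize_stoich(r$products, r$id)
  r$modifiers <- as.character(r$modifiers %||% character())
  refs <- c(names(r$reactants), names(r$products), r$modifiers)
  unknown <- setdiff(refs, species_ids)
  if (length(unknown))
    stop("reaction ", r$id, " references unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(r$reversible)) r$reversible <- NA
  r$reversible <- as.logical(r$reversible)
  r$kinetic_constant <- as.numeric(r$kinetic_constant %||% NA_real_)
  if (!is.na(r$kinetic_constant) && r$kinetic_constant < 0)
    stop("reaction ", r$id, " has negative kinetic constant", call. = FALSE)
  if (is.null(r$kinetic_math)) r$kinetic_math <- NULL
  r[c("id", "name", "reactants", "products", "modifiers", "reversible",
      "kinetic_constant", "kinetic_math")]
}

normalize_stoich <- function(x, rid) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(), character()))
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("reaction ", rid, ": stoichiometries must be named by species id",
         call. = FALSE)
  if (any(x <= 0)) stop("reaction ", rid, ": stoichiometry must be positive",
                        call. = FALSE)
  rounded <- ceiling(x)
  if (any(rounded != x))
    .warn_repair("STOICH_ROUNDED", rid,
                 "non-integer stoichiometry rounded up for discrete counting")
  # collapse duplicate species entries
  tapply_res <- tapply(rounded, names(rounded), sum)
  stats::setNames(as.numeric(tapply_res), names(tapply_res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sbml_model <- function(x, ...) {
  cat("SBML model document\n")
  cat("  species:   ", nrow(x$species), "\n")
  cat("  reactions: ", length(x$reactions), "\n")
  nrev <- sum(vapply(x$reactions, function(r) isTRUE(r$reversible), TRUE))
  nunset <- sum(vapply(x$reactions, function(r) is.na(r$reversible), TRUE))
  cat("  reversible:", nrev, if (nunset) sprintf("(%d unset)", nunset) else "",
      "\n")
  if (length(x$provenance))
    cat("  source:    ", x$provenance$path %||% "<in-memory>",
        sprintf(" (SBML L%sV%s)", x$provenance$level %||% "?",
                x$provenance$version %||% "?"), "\n")
  invisible(x)
}

#' Load an SBML model from file
#'
#' Reads SBML Level 2 or Level 3 documents. Species, reactions, global
#' parameters and compartments are materialized; kinetic laws are kept
#' either as a plain rate constant (when the law is a bare number) or as a
#' parsed rate expression. Repairs are reported as warnings in the form
#' `WARN <code> <element-id> <message>`:
#' * reactions with no `reversible` attribute are recorded as unset
#'   (resolve with [resolve_reversibility()] before graph construction);
#' * species with no initial amount are set to 0;
#' * reactions with no kinetic law are recorded as having none
#'   (assign with [assign_default_kinetics()] before simulation).
#'
#' @param path path to an SBML `.xml` file.
#' @return an `sbml_model`.
#' @seealso [write_model()], [resolve_reversibility()],
#'   [assign_default_kinetics()]
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("cannot read SBML file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  root <- doc
  if (xml2::xml_name(root) != "sbml")
    stop("malformed SBML: root element is <", xml2::xml_name(root),
         ">, expected <sbml>", call. = FALSE)
  level <- xml2::xml_attr(root, "level")
  version <- xml2::xml_attr(root, "version")
  if (!level %in% c("2", "3"))
    stop("unsupported SBML level: ", level, call. = FALSE)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, "./model")
  if (inherits(model_node, "xml_missing"))
    stop("malformed SBML: no <model> element in ", path, call. = FALSE)

  comp_nodes <- xml2::xml_find_all(model_node, "./listOfCompartments/compartment")
  compartments <- stats::setNames(
    vapply(comp_nodes, function(n) {
      s <- xml2::xml_attr(n, "size")
      if (is.na(s)) s <- xml2::xml_attr(n, "volume")
      if (is.na(s)) 1 else as.numeric(s)
    }, 0),
    vapply(comp_nodes, xml2::xml_attr, "", attr = "id"))
  if (!length(compartments)) compartments <- c(cell = 1)

  sp_nodes <- xml2::xml_find_all(model_node, "./listOfSpecies/species")
  species <- data.frame(
    id = vapply(sp_nodes, xml2::xml_attr, "", attr = "id"),
    name = vapply(sp_nodes, function(n) {
      nm <- xml2::xml_attr(n, "name")
      if (is.na(nm)) xml2::xml_attr(n, "id") else nm
    }, ""),
    compartment = vapply(sp_nodes, function(n) {
      cp <- xml2::xml_attr(n, "compartment")
      if (is.na(cp)) names(compartments)[1L] else cp
    }, ""),
    initial_amount = vapply(sp_nodes, function(n) {
      a <- xml2::xml_attr(n, "initialAmount")
      if (is.na(a)) a <- xml2::xml_attr(n, "initialConcentration")
      if (is.na(a)) NA_real_ else as.numeric(a)
    }, 0),
    boundary = vapply(sp_nodes, function(n) {
      b <- xml2::xml_attr(n, "boundaryCondition")
      !is.na(b) && b == "true"
    }, TRUE),
    stringsAsFactors = FALSE)
  miss_amt <- is.na(species$initial_amount)
  for (id in species$id[miss_amt])
    .warn_repair("AMOUNT_MISSING", id, "no initial amount; defaulting to 0")
  species$initial_amount[miss_amt] <- 0

  par_nodes <- xml2::xml_find_all(model_node, "./listOfParameters/parameter")
  parameters <- stats::setNames(
    vapply(par_nodes, function(n) {
      v <- xml2::xml_attr(n, "value")
      if (is.na(v)) NA_real_ else as.numeric(v)
    }, 0),
    vapply(par_nodes, xml2::xml_attr, "", attr = "id"))

  rx_nodes <- xml2::xml_find_all(model_node, "./listOfReactions/reaction")
  reactions <- lapply(rx_nodes, parse_reaction_node, level = level)
  names(reactions) <- vapply(reactions, `[[`, "", "id")

  for (r in reactions) {
    if (is.na(r$reversible))
      .warn_repair("REVERSIBLE_UNSET", r$id,
                   "reversible attribute missing; resolve before graph construction")
    if (is.na(r$kinetic_constant) && is.null(r$kinetic_math))
      .warn_repair("KINETICS_MISSING", r$id,
                   "no kinetic law; assign before simulation")
  }

  new_model(species, reactions, parameters, compartments,
            provenance = list(path = path, level = level, version = version))
}

parse_reaction_node <- function(n, level) {
  id <- xml2::xml_attr(n, "id")
  if (is.na(id)) stop("malformed SBML: reaction with no id", call. = FALSE)
  rev_attr <- xml2::xml_attr(n, "reversible")
  reversible <- if (is.na(rev_attr)) NA else identical(rev_attr, "true")
  read_refs <- function(xpath) {
    refs <- xml2::xml_find_all(n, xpath)
    stats::setNames(
      vapply(refs, function(s) {
        st <- xml2::xml_attr(s, "stoichiometry")
        if (is.na(st)) 1 else as.numeric(st)
      }, 0),
      vapply(refs, xml2::xml_attr, "", attr = "species"))
  }
  reactants <- read_refs("./listOfReactants/speciesReference")
  products <- read_refs("./listOfProducts/speciesReference")
  modifiers <- vapply(
    xml2::xml_find_all(n, "./listOfModifiers/modifierSpeciesReference"),
    xml2::xml_attr, "", attr = "species")

  kinetic_constant <- NA_real_
  kinetic_math <- NULL
  kl <- xml2::xml_find_first(n, "./kineticLaw")
  if (!inherits(kl, "xml_missing")) {
    math <- xml2::xml_find_first(kl, "./math")
    if (!inherits(math, "xml_missing")) {
      expr <- parse_mathml(math)
      # local parameters shadow globals inside the law; substitute values
      lp <- xml2::xml_find_all(
        kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")
      if (length(lp)) {
        lvals <- stats::setNames(
          lapply(lp, function(p) as.numeric(xml2::xml_attr(p, "value"))),
          vapply(lp, xml2::xml_attr, "", attr = "id"))
        expr <- eval(call("substitute", expr, lvals))
      }
      if (is.numeric(expr)) kinetic_constant <- expr else kinetic_math <- expr
    }
  }
  list(id = id, name = xml2::xml_attr(n, "name"),
       reactants = reactants, products = products,
       modifiers = as.character(modifiers), reversible = reversible,
       kinetic_constant = kinetic_constant, kinetic_math = kinetic_math)
}

#' Write a model document as SBML Level 3 Version 1
#'
#' @param model an `sbml_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sbml_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "level=\"3\" version=\"1\">"),
    "  <model id=\"model\">",
    "    <listOfCompartments>")
  for (i in seq_along(model$compartments))
    lines <- c(lines, sprintf(
      "      <compartment id=\"%s\" size=\"%s\" constant=\"true\"/>",
      esc(names(model$compartments)[i]),
      format(model$compartments[[i]], digits = 17)))
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "initialAmount=\"%s\" hasOnlySubstanceUnits=\"true\" ",
             "boundaryCondition=\"%s\" constant=\"false\"/>"),
      esc(s$id), esc(s$name), esc(s$compartment),
      format(s$initial_amount, digits = 17),
      if (s$boundary) "true" else "false"))
  }
  lines <- c(lines, "    </listOfSpecies>")
  if (length(model$parameters)) {
    lines <- c(lines, "    <listOfParameters>")
    for (i in seq_along(model$parameters))
      lines <- c(lines, sprintf(
        "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
        esc(names(model$parameters)[i]),
        format(model$parameters[[i]], digits = 17)))
    lines <- c(lines, "    </listOfParameters>")
  }
  lines <- c(lines, "    <listOfReactions>")
  for (r in model$reactions) {
    if (is.na(r$reversible))
      stop("reaction ", r$id,
           " has unresolved reversibility; run resolve_reversibility()",
           call. = FALSE)
    lines <- c(lines, sprintf(
      "      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" fast=\"false\">",
      esc(r$id), esc(r$name %||% r$id),
      if (r$reversible) "true" else "false"))
    emit_refs <- function(tag, stoich) {
      if (!length(stoich)) return(character())
      c(sprintf("        <listOf%ss>", tag),
        sprintf(paste0("          <%s species=\"%s\" stoichiometry=\"%s\"",
                       " constant=\"true\"/>"),
                "speciesReference", esc(names(stoich)),
                format(stoich, digits = 17)),
        sprintf("        </listOf%ss>", tag))
    }
    lines <- c(lines, emit_refs("Reactant", r$reactants),
               emit_refs("Product", r$products))
    if (length(r$modifiers))
      lines <- c(lines, "        <listOfModifiers>",
                 sprintf("          <modifierSpeciesReference species=\"%s\"/>",
                         esc(r$modifiers)),
                 "        </listOfModifiers>")
    if (!is.null(r$kinetic_math)) {
      lines <- c(lines, "        <kineticLaw>",
                 paste0("          <math xmlns=\"http://www.w3.org/1998/",
                        "Math/MathML\">", deparse_mathml(r$kinetic_math),
                        "</math>"),
                 "        </kineticLaw>")
    } else if (!is.na(r$kinetic_constant)) {
      lines <- c(lines, "        <kineticLaw>",
                 paste0("          <math xmlns=\"http://www.w3.org/1998/",
                        "Math/MathML\">",
                        deparse_mathml(r$kinetic_constant), "</math>"),
                 "        </kineticLaw>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Resolve unset reversibility flags
#'
#' SBML Level 2 semantics default a missing `reversible` attribute to true,
#' while Level 3 requires it; genome-scale reconstructions in the wild ship
#' with the attribute missing on key reactions, which silently deletes graph
#' edges (the backward direction never exists). This operation repairs every
#' unset flag with `default` and applies explicit per-reaction `overrides`.
#'
#' @param model an `sbml_model`.
#' @param default logical, value for unset flags (default `TRUE`, the
#'   Level 2 semantics).
#' @param overrides named logical vector, reaction id -> flag; overrides win
#'   over both the stored flag and the default.
#' @return list with `model` (all flags set) and `changed` (character vector
#'   of reaction ids whose flag changed).
#' @export
resolve_reversibility <- function(model, default = TRUE,
                                  overrides = logical()) {
  stopifnot(inherits(model, "sbml_model"), is.logical(default),
            length(default) == 1L, !is.na(default))
  unknown <- setdiff(names(overrides), names(model$reactions))
  if (length(unknown))
    stop("overrides name unknown reaction id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  changed <- character()
  for (id in names(model$reactions)) {
    old <- model$reactions[[id]]$reversible
    new <- if (id %in% names(overrides)) overrides[[id]]
           else if (is.na(old)) default else old
    if (is.na(old) || new != old) changed <- c(changed, id)
    model$reactions[[id]]$reversible <- new
  }
  list(model = model, changed = changed)
}

#' Assign a default mass-action rate constant to reactions lacking kinetics
#'
#' Genome-scale reconstructions typically ship without kinetic laws; the
#' standard bootstrapping move is to give every reaction the same small
#' arbitrary rate constant and refine from there. Reactions that already
#' carry a constant or a rate expression are untouched.
#'
#' @param model an `sbml_model`.
#' @param k non-negative rate constant (per time unit); default 0.1.
#' @return the model with kinetics filled in; the ids that were changed are
#'   available as `attr(, "changed")`.
#' @export
assign_default_kinetics <- function(model, k = 0.1) {
  stopifnot(inherits(model, "sbml_model"), is.numeric(k), k >= 0)
  changed <- character()
  for (id in names(model$reactions)) {
    r <- model$reactions[[id]]
    if (is.na(r$kinetic_constant) && is.null(r$kinetic_math)) {
      model$reactions[[id]]$kinetic_constant <- k
      changed <- c(changed, id)
    }
  }
  attr(model, "changed") <- changed
  model
}

#' Export a model slice as a standalone model document
#'
#' Builds a new model containing exactly the slice's reactions and species,
#' with initial amounts, kinetics, parameters and compartments copied from
#' the parent model, suitable for writing as SBML and editing in isolation.
#'
#' @param slice a `model_slice` from [slice_model()].
#' @return an `sbml_model`.
#' @export
export_slice <- function(slice) {
  stopifnot(inherits(slice, "model_slice"))
  parent <- slice$parent
  if (!length(slice$reactions))
    stop("empty slice: sink unreachable", call. = FALSE)
  species <- parent$species[parent$species$id %in% slice$species, ,
                            drop = FALSE]
  rownames(species) <- NULL
  reactions <- parent$reactions[names(parent$reactions) %in% slice$reactions]
  comps <- parent$compartments[unique(species$compartment)]
  comps <- comps[!is.na(names(comps))]
  if (!length(comps)) comps <- parent$compartments
  new_model(species, reactions, parent$parameters, comps,
            provenance = list(path = sprintf("<slice sink=%s>", slice$sink),
                              level = "3", version = "1"))
}

#' Merge an edited sub-model back into its original model
#'
#' For every species or reaction id present in `edited`, the original's
#' kinetic constant, rate expression, reversibility and initial amount are
#' replaced by the edited values; ids absent from `edited` are untouched;
#' genuinely new ids are appended. This is the re-insertion step after
#' refining an exported slice.
#'
#' @param original,edited `sbml_model` objects; `edited` is typically an
#'   exported slice after parameter adjustment.
#' @return list with `model` (the merged document) and `changed` (ids whose
#'   stored values actually differ from the original's).
#' @export
merge_slice <- function(original, edited) {
  stopifnot(inherits(original, "sbml_model"), inherits(edited, "sbml_model"))
  clash <- intersect(edited$species$id, names(original$reactions))
  clash <- c(clash, intersect(names(edited$reactions), original$species$id))
  if (length(clash))
    stop("id used as both species and reaction: ",
         paste(unique(clash), collapse = ", "), call. = FALSE)
  changed <- character()
  for (i in seq_len(nrow(edited$species))) {
    s <- edited$species[i, ]
    j <- match(s$id, original$species$id)
    if (is.na(j)) {
      original$species <- rbind(original$species, s)
      changed <- c(changed, s$id)
    } else if (original$species$initial_amount[j] != s$initial_amount ||
               original$species$boundary[j] != s$boundary) {
      original$species$initial_amount[j] <- s$initial_amount
      original$species$boundary[j] <- s$boundary
      changed <- c(changed, s$id)
    }
  }
  for (id in names(edited$reactions)) {
    er <- edited$reactions[[id]]
    orr <- original$reactions[[id]]
    if (is.null(orr)) {
      original$reactions[[id]] <- er
      changed <- c(changed, id)
    } else {
      same <- identical(orr$kinetic_constant, er$kinetic_constant) &&
        identical(orr$kinetic_math, er$kinetic_math) &&
        identical(orr$reversible, er$reversible)
      if (!same) {
        original$reactions[[id]]$kinetic_constant <- er$kinetic_constant
        original$reactions[[id]]$kinetic_math <- er$kinetic_math
        original$reactions[[id]]$reversible <- er$reversible
        changed <- c(changed, id)
      }
    }
  }
  rownames(original$species) <- NULL
  list(model = original, changed = unique(changed))
}

#' Basic size statistics for a model document
#'
#' Reversible reactions count once (the graph layer expands them to two
#' directions, but complexity comparisons use base reaction counts).
#'
#' @param model an `sbml_model`.
#' @return list with `n_reactions`, `n_species`, `n_reversible`, `n_unset`,
#'   `components` (reactions + species).
#' @export
model_stats <- function(model) {
  stopifnot(inherits(model, "sbml_model"))
  list(n_reactions = length(model$reactions),
       n_species = nrow(model$species),
       n_reversible = sum(vapply(model$reactions,
                                 function(r) isTRUE(r$reversible), TRUE)),
       n_unset = sum(vapply(model$reactions,
                            function(r) is.na(r$reversible), TRUE)),
       components = length(model$reactions) + nrow(model$species))
}
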