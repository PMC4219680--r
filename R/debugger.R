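# Software-debugger layer over the SSA engine: breakpoints (on a reaction,
# on a condition, on ensemble outliers), watch snapshots, runtime edits,
# instruction skipping and deadlock escape. A session owns its RNG state so
# that halting and resuming without edits replays exactly like an
# uninterrupted run — breakpoints are observation-only.

#' Open a debugging session on a model
#'
#' @param model an `sbml_model` with reversibility resolved and kinetics
#'   assigned.
#' @param seed integer seed for the session's random stream.
#' @param tmax default time horizon for [run_until_break()].
#' @param cofactors cofactor set used for the session's reaction graph
#'   (predictive weights); see [default_cofactors()].
#' @param eps deadlock threshold on the total propensity.
#' @return an environment of class `debug_session`.
#' @export
debug_session <- function(model, seed = 1L, tmax = Inf,
                          cofactors = default_cofactors(), eps = 1e-12) {
  stopifnot(inherits(model, "sbml_model"))
  s <- ssa_engine(model, eps = eps)
  s$graph <- build_graph(s$directed, cofactors = cofactors)
  s$tmax <- tmax
  s$breakpoints <- list()
  s$next_bp_id <- 1L
  s$pending <- NULL       # list(reaction, tau) drawn but not yet executed
  s$halted <- TRUE        # session starts halted at t = 0
  s$status <- "READY"
  s$transcript <- character()
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s$rng <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  class(s) <- c("debug_session", class(s))
  s
}

#' @export
print.debug_session <- function(x, ...) {
  cat("debug session at t =", format(x$t), "| step", x$step_i,
      "| status", x$status, "\n ",
      length(x$breakpoints), "breakpoint(s);",
      if (!is.null(x$pending)) paste("pending", x$pending$reaction) else
        "nothing pending", "\n")
  invisible(x)
}

rng_restore <- function(s) assign(".Random.seed", s$rng, globalenv())
rng_save <- function(s) s$rng <- get(".Random.seed", globalenv())

#' Take a watch snapshot of the current session state
#'
#' @param session a `debug_session`.
#' @return object of class `watch_record`: `t`, `amounts`, `produced`,
#'   `params`, `compartments`, `fired`, and the current reaction weights
#'   (`weights`, with total `a0`).
#' @export
watch_record <- function(session) {
  props <- engine_propensities(session)
  structure(list(t = session$t, amounts = session$amounts,
                 produced = session$produced, params = session$params,
                 compartments = session$compartments, fired = session$fired,
                 weights = props$a, a0 = props$a0),
            class = "watch_record")
}

#' @export
print.watch_record <- function(x, ...) {
  cat("watch @ t =", format(x$t), "\n")
  nz <- x$amounts[x$amounts > 0 | x$produced > 0]
  df <- data.frame(amount = x$amounts[names(nz)],
                   produced = x$produced[names(nz)])
  print(df)
  invisible(x)
}

# --- predicate mini-language ----------------------------------------------

.pred_ops <- c("<", "<=", ">", ">=", "==", "!=", "&", "&&", "|", "||", "!",
               "(", "+", "-", "*", "/")
.pred_funs <- c("amount", "produced", "param")

validate_predicate <- function(e) {
  if (is.numeric(e) || is.logical(e)) return(invisible(TRUE))
  if (is.name(e)) {
    if (as.character(e) != "t")
      stop("predicate symbol not allowed: `", as.character(e),
           "` (wrap species/parameters in amount()/produced()/param())",
           call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    if (fn %in% .pred_funs) {
      if (length(e) != 2L || !(is.name(e[[2L]]) || is.character(e[[2L]])))
        stop("predicate: ", fn, "() takes a single bare id", call. = FALSE)
      return(invisible(TRUE))
    }
    if (!fn %in% .pred_ops)
      stop("predicate function not allowed: `", fn, "`", call. = FALSE)
    for (arg in as.list(e)[-1L]) validate_predicate(arg)
    return(invisible(TRUE))
  }
  stop("unsupported predicate element", call. = FALSE)
}

parse_predicate <- function(text) {
  e <- tryCatch(str2lang(text),
                error = function(err)
                  stop("cannot parse predicate: ", conditionMessage(err),
                       call. = FALSE))
  validate_predicate(e)
  e
}

eval_predicate <- function(e, session) {
  env <- new.env(parent = baseenv())
  assign("t", session$t, env)
  lookup <- function(table, kind) function(id) {
    id <- as.character(substitute(id))
    v <- table[[id]]
    if (is.null(v) || is.na(v))
      stop("predicate references unknown ", kind, ": ", id, call. = FALSE)
    v
  }
  amounts <- session$amounts; produced <- session$produced
  params <- session$params
  assign("amount", function(id) {
    id <- as.character(substitute(id))
    if (!id %in% names(amounts)) stop("unknown species: ", id, call. = FALSE)
    amounts[[id]]
  }, env)
  assign("produced", function(id) {
    id <- as.character(substitute(id))
    if (!id %in% names(produced)) stop("unknown species: ", id, call. = FALSE)
    produced[[id]]
  }, env)
  assign("param", function(id) {
    id <- as.character(substitute(id))
    if (!id %in% names(params)) stop("unknown parameter: ", id, call. = FALSE)
    params[[id]]
  }, env)
  isTRUE(eval(e, env))
}

# --- breakpoints -----------------------------------------------------------

#' Add a breakpoint to a session
#'
#' Exactly one of `reaction` and `condition` must be given. A reaction
#' breakpoint fires just before the named directed reaction executes (so
#' the instruction can still be skipped); a condition breakpoint fires
#' after a step, the first time its predicate switches to true. Predicates
#' are a deliberately tiny language: comparisons, boolean operators and
#' arithmetic over `amount(id)`, `produced(id)`, `param(id)` and `t`.
#'
#' @param session a `debug_session`.
#' @param reaction directed reaction id (base id also accepted; it matches
#'   the forward direction).
#' @param condition predicate string, e.g. `"amount(atp) < 10"` or
#'   `"t >= 5"`.
#' @return the integer breakpoint id.
#' @export
add_breakpoint <- function(session, reaction = NULL, condition = NULL) {
  stopifnot(inherits(session, "debug_session"))
  if (is.null(reaction) == is.null(condition))
    stop("give exactly one of `reaction` and `condition`", call. = FALSE)
  bp <- list(id = session$next_bp_id, enabled = TRUE, hits = 0L)
  if (!is.null(reaction)) {
    if (!reaction %in% session$ids)
      stop("unknown reaction id: ", reaction, call. = FALSE)
    bp$kind <- "REACTION"
    bp$reaction <- reaction
  } else {
    bp$kind <- "CONDITION"
    bp$predicate <- parse_predicate(condition)
    bp$predicate_text <- condition
    bp$last <- eval_predicate(bp$predicate, session)
  }
  session$breakpoints[[as.character(bp$id)]] <- bp
  session$next_bp_id <- session$next_bp_id + 1L
  bp$id
}

#' Register outlier breakpoints from a simulation ensemble
#'
#' For each watched species, a breakpoint fires when the live run leaves
#' the ensemble envelope `mean +/- c * SD` at the matched grid time
#' (last-observation-carried-forward alignment of the live time onto the
#' envelope grid).
#'
#' @param session a `debug_session`.
#' @param ensemble an `ssa_ensemble` from [multi_simulate()].
#' @param c SD multiplier (>= 0).
#' @param species subset of the ensemble's species; default all.
#' @return integer vector of breakpoint ids.
#' @export
outlier_breaks <- function(session, ensemble, c = 3, species = NULL) {
  stopifnot(inherits(session, "debug_session"),
            inherits(ensemble, "ssa_ensemble"), c >= 0)
  species <- species %||% ensemble$species
  ids <- integer()
  for (sp in species) {
    bp <- list(id = session$next_bp_id, enabled = TRUE, hits = 0L,
               kind = "OUTLIER", species = sp, c = c, envelope = ensemble,
               # first envelope grid point strictly ahead of the session
               next_grid = findInterval(session$t, ensemble$grid) + 1L)
    session$breakpoints[[as.character(bp$id)]] <- bp
    session$next_bp_id <- session$next_bp_id + 1L
    ids <- c(ids, bp$id)
  }
  ids
}

#' Enable or disable a breakpoint
#' @param session a `debug_session`.
#' @param id breakpoint id.
#' @param enabled flag.
#' @return the id, invisibly.
#' @export
set_breakpoint_enabled <- function(session, id, enabled = TRUE) {
  key <- as.character(id)
  if (is.null(session$breakpoints[[key]]))
    stop("no breakpoint with id ", id, call. = FALSE)
  session$breakpoints[[key]]$enabled <- enabled
  invisible(id)
}

# The live run's value AT a grid time g is its last-observation-carried-
# forward amount: constant since the previous firing. So when a step jumps
# the clock past grid points, those points are scored with the pre-step
# amounts, exactly as sample_trajectory() would resample them.
check_outlier <- function(bp, key, session, prev_amounts) {
  env <- bp$envelope
  fired <- FALSE
  while (bp$next_grid <= length(env$grid) &&
         env$grid[bp$next_grid] < session$t) {
    g <- bp$next_grid
    bp$next_grid <- g + 1L
    mu <- env$mean[g, bp$species]
    sdv <- env$sd[g, bp$species]
    if (abs(prev_amounts[[bp$species]] - mu) > bp$c * sdv) {
      fired <- TRUE
      break
    }
  }
  session$breakpoints[[key]]$next_grid <- bp$next_grid
  fired
}

# evaluate post-step breakpoints; returns id of the first that fires or NULL
post_step_break <- function(session, prev_amounts = session$amounts) {
  for (key in names(session$breakpoints)) {
    bp <- session$breakpoints[[key]]
    if (!bp$enabled) next
    if (bp$kind == "CONDITION") {
      cur <- eval_predicate(bp$predicate, session)
      fired <- cur && !bp$last
      session$breakpoints[[key]]$last <- cur
      if (fired) {
        session$breakpoints[[key]]$hits <- bp$hits + 1L
        return(bp$id)
      }
    } else if (bp$kind == "OUTLIER") {
      if (check_outlier(bp, key, session, prev_amounts)) {
        session$breakpoints[[key]]$hits <- bp$hits + 1L
        return(bp$id)
      }
    }
  }
  NULL
}

reaction_break <- function(session, reaction) {
  base <- session$directed[[reaction]]$base_id
  for (key in names(session$breakpoints)) {
    bp <- session$breakpoints[[key]]
    if (bp$enabled && bp$kind == "REACTION" &&
        (bp$reaction == reaction || bp$reaction == base)) {
      session$breakpoints[[key]]$hits <- bp$hits + 1L
      return(bp$id)
    }
  }
  NULL
}

# --- execution control -----------------------------------------------------

halt <- function(session, status, breakpoint = NULL, deadlock = NULL) {
  session$halted <- TRUE
  session$status <- status
  rng_save(session)
  structure(list(status = status, breakpoint = breakpoint,
                 deadlock = deadlock, record = watch_record(session),
                 t = session$t, step = session$step_i),
            class = "debug_halt")
}

#' @export
print.debug_halt <- function(x, ...) {
  cat("[", x$status, "] t =", format(x$t), "after", x$step, "steps")
  if (!is.null(x$breakpoint)) cat(" (breakpoint", x$breakpoint, ")")
  cat("\n")
  if (!is.null(x$deadlock)) print(x$deadlock)
  invisible(x)
}

#' Resume the simulation until the next halt
#'
#' Runs the SSA loop until a breakpoint fires, a deadlock is reached, the
#' session's time horizon is crossed (`COMPLETED`), or `max_steps`
#' firings have executed (`PAUSED`). The returned halt carries a
#' [watch_record()] snapshot; the session remains resumable.
#'
#' @param session a `debug_session`.
#' @param max_steps cap on firings for this call (use 1 to single-step).
#' @return a `debug_halt` with `status` one of `BREAK`, `DEADLOCK`,
#'   `COMPLETED`, `PAUSED`.
#' @export
run_until_break <- function(session, max_steps = Inf) {
  stopifnot(inherits(session, "debug_session"))
  rng_restore(session)
  session$halted <- FALSE
  steps <- 0L
  repeat {
    if (!is.null(session$pending)) {
      p <- session$pending
      session$pending <- NULL
      prev <- session$amounts
      engine_execute(session, p$reaction, p$tau)
      steps <- steps + 1L
      bp <- post_step_break(session, prev)
      if (!is.null(bp)) return(halt(session, "BREAK", breakpoint = bp))
      if (steps >= max_steps) return(halt(session, "PAUSED"))
      next
    }
    sel <- engine_select(session)
    if (inherits(sel, "deadlock_report"))
      return(halt(session, "DEADLOCK", deadlock = sel))
    if (session$t + sel$tau > session$tmax) {
      session$t <- session$tmax
      return(halt(session, "COMPLETED"))
    }
    bp <- reaction_break(session, sel$reaction)
    if (!is.null(bp)) {
      session$pending <- list(reaction = sel$reaction, tau = sel$tau)
      return(halt(session, "BREAK", breakpoint = bp))
    }
    prev <- session$amounts
    engine_execute(session, sel$reaction, sel$tau)
    steps <- steps + 1L
    bp <- post_step_break(session, prev)
    if (!is.null(bp)) return(halt(session, "BREAK", breakpoint = bp))
    if (steps >= max_steps) return(halt(session, "PAUSED"))
  }
}

#' Edit the halted session's state
#'
#' Applies a named map of edits while the session is halted: names that
#' match a species set its amount (negative values are rejected), names
#' that match a global parameter set its value, and names that match a
#' reaction (base or directed id) set its kinetic constant. Propensities
#' and predictive weights are recomputed implicitly (they are derived from
#' state on demand).
#'
#' @param session a halted `debug_session`.
#' @param edits named numeric vector.
#' @return a post-edit [watch_record()].
#' @export
modify_session <- function(session, edits) {
  stopifnot(inherits(session, "debug_session"))
  if (!session$halted)
    stop("session must be halted (at a break or deadlock) to modify",
         call. = FALSE)
  for (nm in names(edits)) {
    v <- as.numeric(edits[[nm]])
    if (nm %in% names(session$amounts)) {
      if (v < 0) stop("negative amount for ", nm, " rejected", call. = FALSE)
      session$amounts[[nm]] <- v
    } else if (nm %in% names(session$params)) {
      session$params[[nm]] <- v
    } else if (nm %in% session$ids ||
               nm %in% names(session$model$reactions)) {
      if (v < 0) stop("negative kinetic constant for ", nm, " rejected",
                      call. = FALSE)
      targets <- session$ids[vapply(session$directed, function(n)
        n$id == nm || n$base_id == nm, TRUE)]
      for (id in targets) session$directed[[id]]$kinetic_constant <- v
    } else {
      stop("unknown id in edits: ", nm, call. = FALSE)
    }
  }
  # deadlocks may be escapable now; let the caller resume
  if (session$status == "DEADLOCK") session$status <- "READY"
  watch_record(session)
}

#' Skip the pending instruction
#'
#' When the session halted just before a reaction (a reaction breakpoint),
#' that reaction is excluded from the next selection round; time then
#' advances according to whichever reaction is chosen instead. If no other
#' reaction is available the skip produces an immediate deadlock report.
#'
#' @param session a halted `debug_session` with a pending reaction.
#' @return a [watch_record()] (state unchanged), or a `deadlock_report` if
#'   skipping leaves nothing executable.
#' @export
skip_instruction <- function(session) {
  stopifnot(inherits(session, "debug_session"))
  if (is.null(session$pending)) {
    message("nothing pending to skip")
    return(watch_record(session))
  }
  skipped <- session$pending$reaction
  session$pending <- NULL
  session$skip_once <- union(session$skip_once, skipped)
  props <- engine_propensities(session, exclude = session$skip_once)
  if (props$a0 == 0) {
    session$status <- "DEADLOCK"
    return(deadlock_report("NO_AVAILABLE_REACTANTS", session,
                           paste("no reaction available after skipping",
                                 skipped)))
  }
  watch_record(session)
}

#' Predictive and reaction weights at the session's current state
#'
#' @param session a `debug_session`.
#' @return data.frame with columns `reaction`, `reaction_weight`,
#'   `predictive_weight`, ordered by directed reaction id.
#' @export
session_weights <- function(session) {
  stopifnot(inherits(session, "debug_session"))
  st <- list(amounts = session$amounts, params = session$params,
             compartments = session$compartments)
  alpha <- predictive_weights(session$graph, st)
  data.frame(reaction = names(alpha),
             reaction_weight = as.numeric(attr(alpha, "reaction_weight")),
             predictive_weight = as.numeric(alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}
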