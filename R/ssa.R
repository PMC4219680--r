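# Gillespie direct-method stochastic simulation. The engine keeps integer
# molecule counts, cumulative per-species production counters and a complete
# event log; the debugger layer drives the same core step so that a halted
# and resumed session replays exactly like an uninterrupted run.

#' Propensity (reaction weight) of one directed reaction
#'
#' For a mass-action reaction the weight is the rate constant times the
#' number of distinct reactant combinations,
#' `k * prod(choose(n_i, s_i))` over reactants `i` with amount `n_i` and
#' stoichiometry `s_i`; it is 0 whenever any reactant is below its
#' stoichiometry. When the reaction carries a rate expression the weight is
#' that expression evaluated on the current amounts and parameters, clamped
#' at 0, and likewise forced to 0 when reactants are insufficient.
#'
#' @param reaction a directed reaction (element of
#'   [expand_directions()] output) or a model reaction entry.
#' @param state list with `amounts` (named numeric), optionally `params`
#'   and `compartments`.
#' @return non-negative numeric weight.
#' @export
propensity <- function(reaction, state) {
  amounts <- state$amounts
  s <- reaction$reactants
  if (length(s)) {
    n <- amounts[names(s)]
    n[is.na(n)] <- 0
    if (any(n < s)) return(0)
  }
  if (!is.null(reaction$kinetic_math)) {
    vals <- c(as.list(amounts), as.list(state$params %||% numeric()),
              as.list(state$compartments %||% numeric()))
    return(eval_kinetic_math(reaction$kinetic_math, vals))
  }
  k <- reaction$kinetic_constant
  if (is.na(k))
    stop("reaction ", reaction$id,
         " has no kinetic law; run assign_default_kinetics()", call. = FALSE)
  if (!length(s)) return(k)
  k * prod(choose(amounts[names(s)], s))
}

#' Propensities of all directed reactions in a state
#'
#' @param directed a `directed_reactions` object.
#' @inheritParams propensity
#' @return list with `a` (named weights, in lexicographic id order) and
#'   `a0` (their sum).
#' @export
propensities <- function(directed, state) {
  ids <- sort(names(directed))
  a <- vapply(ids, function(id) propensity(directed[[id]], state), 0)
  list(a = a, a0 = sum(a))
}

# --- internal engine -------------------------------------------------------

# Build the mutable engine environment shared by simulate_ssa() and the
# debugger session. Reaction order is fixed lexicographically so the
# cumulative-sum selection is deterministic across platforms.
ssa_engine <- function(model, eps = 1e-12) {
  directed <- expand_directions(model)
  ids <- sort(names(directed))
  e <- new.env(parent = emptyenv())
  e$model <- model
  e$directed <- directed[ids]
  class(e$directed) <- "directed_reactions"
  e$ids <- ids
  e$eps <- eps
  e$t <- 0
  e$step_i <- 0L
  e$amounts <- stats::setNames(as.numeric(model$species$initial_amount),
                               model$species$id)
  e$boundary <- stats::setNames(model$species$boundary, model$species$id)
  e$produced <- stats::setNames(numeric(nrow(model$species)),
                                model$species$id)
  e$fired <- stats::setNames(integer(length(ids)), ids)
  e$params <- model$parameters
  e$compartments <- model$compartments
  e$disabled <- character()     # reactions disabled until re-enabled
  e$skip_once <- character()    # reactions excluded from the next selection
  e$events <- list()            # grown in blocks
  e$n_events <- 0L
  e
}

engine_state <- function(e) {
  list(t = e$t, amounts = e$amounts, produced = e$produced,
       params = e$params, compartments = e$compartments, fired = e$fired)
}

engine_propensities <- function(e, exclude = character()) {
  st <- list(amounts = e$amounts, params = e$params,
             compartments = e$compartments)
  a <- vapply(e$ids, function(id) {
    if (id %in% e$disabled || id %in% exclude) return(0)
    propensity(e$directed[[id]], st)
  }, 0)
  list(a = a, a0 = sum(a))
}

# Select the next reaction and waiting time. Returns either
# list(reaction, tau) or a deadlock report. Consumes the one-round skip set.
engine_select <- function(e) {
  props <- engine_propensities(e, exclude = e$skip_once)
  e$skip_once <- character()
  if (props$a0 == 0)
    return(deadlock_report("NO_AVAILABLE_REACTANTS", e,
                           "no reaction has all reactants available"))
  if (props$a0 < e$eps)
    return(deadlock_report("RATES_TOO_LOW", e, sprintf(
      "total propensity %.3g below threshold %.3g", props$a0, e$eps)))
  tau <- stats::rexp(1L, rate = props$a0)
  u <- stats::runif(1L)
  idx <- findInterval(u * props$a0, cumsum(props$a)) + 1L
  idx <- min(idx, length(props$a))
  list(reaction = e$ids[[idx]], tau = tau, a = props$a, a0 = props$a0)
}

# Apply one selected reaction: advance time, update counts, log the event.
engine_execute <- function(e, reaction, tau) {
  e$t <- e$t + tau
  e$step_i <- e$step_i + 1L
  node <- e$directed[[reaction]]
  for (s in names(node$reactants))
    if (!e$boundary[[s]]) e$amounts[[s]] <- e$amounts[[s]] - node$reactants[[s]]
  for (s in names(node$products)) {
    if (!e$boundary[[s]]) e$amounts[[s]] <- e$amounts[[s]] + node$products[[s]]
    e$produced[[s]] <- e$produced[[s]] + node$products[[s]]
  }
  if (any(e$amounts < 0))
    stop("internal error: negative amount after ", reaction, call. = FALSE)
  e$fired[[reaction]] <- e$fired[[reaction]] + 1L
  e$n_events <- e$n_events + 1L
  if (e$n_events > length(e$events))
    e$events <- c(e$events, vector("list", max(64L, length(e$events))))
  e$events[[e$n_events]] <- list(step = e$step_i, time = e$t,
                                 reaction = reaction)
  invisible(e)
}

deadlock_report <- function(reason, e, detail) {
  structure(list(reason = reason, t = e$t, snapshot = engine_state(e),
                 detail = detail),
            class = "deadlock_report")
}

#' @export
print.deadlock_report <- function(x, ...) {
  cat("simulation deadlock at t =", format(x$t), "—", x$reason, "\n ",
      x$detail, "\n")
  invisible(x)
}

event_log_df <- function(e) {
  ev <- e$events[seq_len(e$n_events)]
  data.frame(step = vapply(ev, `[[`, 0L, "step"),
             time = vapply(ev, `[[`, 0, "time"),
             reaction = vapply(ev, `[[`, "", "reaction"),
             stringsAsFactors = FALSE)
}

# --- public simulation -----------------------------------------------------

#' Run a stochastic simulation
#'
#' Gillespie direct method: initialize at `t = 0` with the model's initial
#' amounts; repeatedly compute reaction weights, draw the waiting time from
#' an exponential with rate `a0` and the next reaction with probability
#' `a_r / a0`; execute and iterate until the time horizon, the step limit,
#' or a deadlock (no available reactants, or total rate below `eps`).
#' Boundary-condition species are never changed by firings (their
#' production counters still accumulate).
#'
#' @param model an `sbml_model` with reversibility resolved and kinetics
#'   assigned.
#' @param tmax time horizon (arbitrary time units); `Inf` allowed if
#'   `max_steps` is finite.
#' @param max_steps cap on the number of reaction firings.
#' @param seed integer seed; identical model + seed + horizon give a
#'   bit-identical event log. `NULL` uses the current RNG state.
#' @param watch species ids to record; default all species.
#' @param eps total-propensity threshold below which the run is declared
#'   deadlocked with reason `RATES_TOO_LOW`.
#' @return an object of class `ssa_trajectory`: `times`, `amounts` (matrix,
#'   one row per recorded time, one column per watched species), `events`
#'   (data.frame step/time/reaction), `terminal` (`"COMPLETED"`,
#'   `"DEADLOCK"`), `deadlock` (report or `NULL`), `final` (full state),
#'   `produced`, `fired`.
#' @export
simulate_ssa <- function(model, tmax = Inf, max_steps = Inf, seed = NULL,
                         watch = NULL, eps = 1e-12) {
  stopifnot(inherits(model, "sbml_model"))
  if (!is.finite(tmax) && !is.finite(max_steps))
    stop("one of tmax and max_steps must be finite", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  e <- ssa_engine(model, eps = eps)
  watch <- watch %||% model$species$id
  unknown <- setdiff(watch, model$species$id)
  if (length(unknown))
    stop("unknown watch species: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  rec_times <- numeric(64L); rec <- vector("list", 64L); nr <- 0L
  record <- function() {
    nr <<- nr + 1L
    if (nr > length(rec_times)) {
      rec_times <<- c(rec_times, numeric(length(rec_times)))
      rec <<- c(rec, vector("list", length(rec)))
    }
    rec_times[nr] <<- e$t
    rec[[nr]] <<- e$amounts[watch]
  }
  record()
  terminal <- "COMPLETED"
  deadlock <- NULL
  while (e$step_i < max_steps) {
    sel <- engine_select(e)
    if (inherits(sel, "deadlock_report")) {
      terminal <- "DEADLOCK"
      deadlock <- sel
      break
    }
    if (e$t + sel$tau > tmax) {
      e$t <- tmax
      break
    }
    engine_execute(e, sel$reaction, sel$tau)
    record()
  }
  # after a deadlock nothing can fire, so the state is known constant out to
  # the horizon: report coverage to tmax when it is finite
  t_end <- if (terminal == "DEADLOCK" && is.finite(tmax)) tmax else e$t
  structure(list(times = rec_times[seq_len(nr)],
                 amounts = do.call(rbind, rec[seq_len(nr)]),
                 watch = watch,
                 events = event_log_df(e),
                 terminal = terminal, deadlock = deadlock,
                 final = engine_state(e),
                 produced = e$produced, fired = e$fired,
                 t_end = t_end),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("SSA trajectory:", nrow(x$events), "events, t_end =",
      format(x$t_end), "—", x$terminal, "\n")
  invisible(x)
}

#' Resample a trajectory on a time grid
#'
#' Last-observation-carried-forward: the value at grid time `g` is the
#' amount after the last event with time `<= g`.
#'
#' @param traj an `ssa_trajectory`.
#' @param grid increasing numeric vector of times.
#' @param species species ids (subset of the trajectory's watch list);
#'   default all watched.
#' @return matrix with `length(grid)` rows and one column per species.
#' @export
sample_trajectory <- function(traj, grid, species = NULL) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  species <- species %||% traj$watch
  unknown <- setdiff(species, traj$watch)
  if (length(unknown))
    stop("species not watched: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  idx <- findInterval(grid, traj$times)
  idx[idx < 1L] <- 1L
  m <- traj$amounts[idx, species, drop = FALSE]
  rownames(m) <- format(grid)
  m
}

#' Run replicate simulations and compute a mean/SD envelope
#'
#' @inheritParams simulate_ssa
#' @param n number of replicates (>= 1).
#' @param seeds explicit integer seeds (length `n`); default
#'   `seed + 0:(n-1)`.
#' @param grid_dt grid spacing for the envelope (default 1 time unit).
#' @return object of class `ssa_ensemble`: `trajectories` (list), `grid`,
#'   `mean` and `sd` (grid x species matrices), `species`.
#' @export
multi_simulate <- function(model, n, tmax, seed = 1L, seeds = NULL,
                           watch = NULL, max_steps = Inf, grid_dt = 1,
                           eps = 1e-12) {
  stopifnot(n >= 1, is.finite(tmax))
  seeds <- as.integer(seeds %||% (seed + seq_len(n) - 1L))
  if (length(seeds) != n) stop("need one seed per replicate", call. = FALSE)
  watch <- watch %||% model$species$id
  trajs <- lapply(seeds, function(s)
    simulate_ssa(model, tmax = tmax, max_steps = max_steps, seed = s,
                 watch = watch, eps = eps))
  grid <- seq(0, tmax, by = grid_dt)
  cube <- lapply(trajs, sample_trajectory, grid = grid, species = watch)
  mean_m <- Reduce(`+`, cube) / n
  sd_m <- if (n == 1L) {
    m <- mean_m; m[] <- 0; m
  } else {
    sq <- Reduce(`+`, lapply(cube, function(m) (m - mean_m)^2))
    sqrt(sq / (n - 1L))
  }
  structure(list(trajectories = trajs, grid = grid, mean = mean_m,
                 sd = sd_m, species = watch, seeds = seeds),
            class = "ssa_ensemble")
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat("SSA ensemble:", length(x$trajectories), "replicates on grid [0,",
      format(max(x$grid)), "] x", length(x$species), "species\n")
  invisible(x)
}

#' Write a trajectory (and its event log) to CSV files
#'
#' @param traj an `ssa_trajectory`.
#' @param prefix output path prefix; writes `<prefix>_trajectory.csv`
#'   (header `time,<species...>`) and `<prefix>_events.csv`
#'   (`step,time,reaction_id`).
#' @return character vector of the two paths, invisibly.
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  tpath <- paste0(prefix, "_trajectory.csv")
  epath <- paste0(prefix, "_events.csv")
  df <- data.frame(time = traj$times, traj$amounts, check.names = FALSE)
  utils::write.csv(df, tpath, row.names = FALSE, quote = FALSE)
  ev <- traj$events
  names(ev) <- c("step", "time", "reaction_id")
  utils::write.csv(ev, epath, row.names = FALSE, quote = FALSE)
  invisible(c(tpath, epath))
}
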