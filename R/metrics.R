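# Model-comparison metrics: component counting, stabilization detection on
# an integer time grid, and the behavior-difference percentage used to
# score a reduced model against its original.

#' Component count of a model
#'
#' Model size as the sum of (base) reactions and species.
#'
#' @param model an `sbml_model`.
#' @return integer component count.
#' @export
model_size <- function(model) {
  stopifnot(inherits(model, "sbml_model"))
  length(model$reactions) + nrow(model$species)
}

#' Detect stabilization of a watched species
#'
#' The trajectory is resampled on an integer time-unit grid
#' (last-observation-carried-forward). Stabilization time `t_star` is the
#' first grid time such that for every grid time `u` in
#' `(t_star, t_star + window]` the amount differs from `x(t_star)` by less
#' than `tol` relative to `max(x(t_star), 1)` (the floor of 1 avoids
#' division by zero at zero plateaus). `x_star` is the amount at `t_star`.
#'
#' @param traj an `ssa_trajectory` watching `species`.
#' @param species species id.
#' @param window look-ahead in time units (default 10).
#' @param tol relative tolerance (default 0.01, i.e. 1%).
#' @return object of class `stabilization_result`: `stabilized` (flag),
#'   `t_star`, `x_star` (NA when not stabilized).
#' @export
stabilization <- function(traj, species, window = 10, tol = 0.01) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  t_end <- floor(traj$t_end)
  res <- structure(list(stabilized = FALSE, t_star = NA_real_,
                        x_star = NA_real_, species = species),
                   class = "stabilization_result")
  if (t_end < window) return(res)
  grid <- 0:t_end
  x <- as.numeric(sample_trajectory(traj, grid, species))
  for (i in seq_len(t_end - window + 1L)) {   # grid index of candidate t_star
    x0 <- x[i]
    ahead <- x[(i + 1L):(i + window)]
    if (all(abs(ahead - x0) / max(x0, 1) < tol)) {
      res$stabilized <- TRUE
      res$t_star <- grid[i]
      res$x_star <- x0
      return(res)
    }
  }
  res
}

#' @export
print.stabilization_result <- function(x, ...) {
  if (x$stabilized)
    cat(sprintf("%s stabilized at t = %g with amount %g\n",
                x$species, x$t_star, x$x_star))
  else cat(x$species, "did not stabilize within the trajectory\n")
  invisible(x)
}

#' Behavior difference between two stabilization results
#'
#' Sum of the percentage differences — relative to the original model — in
#' stabilization time and stabilization amount:
#' `100 * |t_o - t_c| / t_o + 100 * |x_o - x_c| / x_o`.
#'
#' @param orig stabilization of the original model (`t_star` and `x_star`
#'   must be positive), or a numeric pair `c(t_star, x_star)`.
#' @param other stabilization of the candidate model, same forms accepted.
#' @return numeric percentage (>= 0; 0 for identical pairs).
#' @export
behavior_difference <- function(orig, other) {
  as_pair <- function(x, label) {
    if (inherits(x, "stabilization_result")) {
      if (!x$stabilized)
        stop(label, " trajectory did not stabilize", call. = FALSE)
      c(x$t_star, x$x_star)
    } else {
      stopifnot(is.numeric(x), length(x) == 2L)
      as.numeric(x)
    }
  }
  o <- as_pair(orig, "original")
  c_ <- as_pair(other, "candidate")
  if (o[1] <= 0 || o[2] <= 0)
    stop("original stabilization time and amount must be positive",
         call. = FALSE)
  100 * abs(o[1] - c_[1]) / o[1] + 100 * abs(o[2] - c_[2]) / o[2]
}

#' Compare candidate models against an original
#'
#' Simulates every model with identical settings, detects stabilization of
#' the watched species, and reports per model the component count, the
#' stabilization pair and the behavior difference versus the original.
#' Wall-clock and memory are deliberately not reported (hardware-bound).
#'
#' @param original an `sbml_model`.
#' @param candidates named list of `sbml_model` objects (names label rows).
#' @param species watched species id (must exist in every model).
#' @param tmax simulation horizon.
#' @param seed integer seed (each model simulated with the same seed).
#' @param window,tol stabilization parameters, see [stabilization()].
#' @param max_steps step cap passed to [simulate_ssa()].
#' @return data.frame with columns `model`, `components`, `t_star`,
#'   `x_star`, `behavior_diff_pct`.
#' @export
compare_report <- function(original, candidates, species, tmax, seed = 1L,
                           window = 10, tol = 0.01, max_steps = Inf) {
  stopifnot(inherits(original, "sbml_model"))
  models <- c(list(original = original), candidates)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- c("original", paste0("candidate_", seq_along(candidates)))
  stabs <- lapply(models, function(m) {
    traj <- simulate_ssa(m, tmax = tmax, max_steps = max_steps, seed = seed,
                         watch = species)
    stabilization(traj, species, window = window, tol = tol)
  })
  orig_stab <- stabs[[1L]]
  data.frame(
    model = names(models),
    components = vapply(models, model_size, 0L),
    t_star = vapply(stabs, `[[`, 0, "t_star"),
    x_star = vapply(stabs, `[[`, 0, "x_star"),
    behavior_diff_pct = vapply(stabs, function(s) {
      if (!s$stabilized || !orig_stab$stabilized) return(NA_real_)
      behavior_difference(orig_stab, s)
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}
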