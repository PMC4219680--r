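# Breakpoints, watch records, runtime edits, skipping, outlier envelopes.

test_that("a reaction breakpoint halts before the reaction executes", {
  m <- make_fixture("CHAIN", n = 3)
  s <- debug_session(m, seed = 21)
  bid <- add_breakpoint(s, reaction = "R2")
  h <- run_until_break(s)
  expect_identical(h$status, "BREAK")
  expect_identical(h$breakpoint, bid)
  expect_equal(h$record$fired[["R2"]], 0L)        # not yet executed
  expect_identical(s$pending$reaction, "R2")
  # resuming executes the pending firing first
  h2 <- run_until_break(s, max_steps = 1)
  expect_equal(s$fired[["R2"]], 1L)
})

test_that("a condition breakpoint fires the first time its predicate turns true", {
  m <- make_fixture("CHAIN", n = 3, k = 0.2)
  ref <- simulate_ssa(m, max_steps = 10000, seed = 33)
  t_expect <- ref$events$time[ref$events$time >= 5][1]

  s <- debug_session(m, seed = 33)
  add_breakpoint(s, condition = "t >= 5.0")
  h <- run_until_break(s)
  expect_identical(h$status, "BREAK")
  expect_equal(h$t, t_expect)

  # a predicate that can never become true lets the run finish
  m2 <- make_fixture("CHAIN", n = 2)
  s2 <- debug_session(m2, seed = 1, tmax = 1000)
  add_breakpoint(s2, condition = "amount(A1) > 1000")
  h2 <- run_until_break(s2)
  expect_identical(h2$status, "DEADLOCK")          # chain exhausts instead
})

test_that("predicates are validated and reject anything outside the mini-language", {
  m <- make_fixture("CHAIN", n = 2)
  s <- debug_session(m, seed = 1)
  expect_error(add_breakpoint(s, condition = "amount(A1) <"), "parse")
  expect_error(add_breakpoint(s, condition = "system('ls')"), "not allowed")
  expect_error(add_breakpoint(s, condition = "A1 > 5"), "not allowed")
  expect_silent(add_breakpoint(s, condition = "amount(A1) + produced(A2) > 3"))
})

test_that("breakpoints are observation-only: halted runs replay identically", {
  m <- make_fixture("MINI_GLYCOLYSIS")
  ref <- simulate_ssa(m, max_steps = 120, seed = 13)

  s <- debug_session(m, seed = 13)
  add_breakpoint(s, reaction = "R_PFK")
  add_breakpoint(s, condition = "produced(pg3) >= 2")
  steps_done <- 0L
  while (steps_done < 120L) {
    h <- run_until_break(s, max_steps = 120L - steps_done)
    steps_done <- s$step_i
    if (h$status %in% c("DEADLOCK", "COMPLETED")) break
  }
  got <- s$events[seq_len(s$n_events)]
  expect_equal(length(got), nrow(ref$events))
  expect_identical(vapply(got, `[[`, "", "reaction"), ref$events$reaction)
  expect_equal(vapply(got, `[[`, 0, "time"), ref$events$time)

  # disabled breakpoints never fire and never perturb the stream
  s2 <- debug_session(m, seed = 13)
  bid <- add_breakpoint(s2, reaction = "R_PFK")
  set_breakpoint_enabled(s2, bid, FALSE)
  h2 <- run_until_break(s2, max_steps = 120)
  expect_false(h2$status == "BREAK")
  expect_identical(vapply(s2$events[seq_len(s2$n_events)], `[[`, "",
                          "reaction"),
                   ref$events$reaction)
})

test_that("watch records report produced amounts consistent with the event log", {
  m <- make_fixture("MINI_GLYCOLYSIS")
  s <- debug_session(m, seed = 5)
  run_until_break(s, max_steps = 60)
  rec <- watch_record(s)
  ev <- data.frame(reaction = vapply(s$events[seq_len(s$n_events)], `[[`, "",
                                     "reaction"))
  d <- expand_directions(m)
  for (sp in names(rec$produced)) {
    expected <- sum(vapply(ev$reaction, function(rid) {
      p <- d[[rid]]$products
      if (sp %in% names(p)) p[[sp]] else 0
    }, 0))
    expect_equal(unname(rec$produced[[sp]]), expected)
  }
})

test_that("runtime edits change weights proportionally and can escape deadlock", {
  m <- make_fixture("CHAIN", n = 2, init = c(A1 = 1))
  s <- debug_session(m, seed = 2)
  h <- run_until_break(s)                 # one firing then deadlock
  expect_identical(h$status, "DEADLOCK")
  expect_identical(h$deadlock$reason, "NO_AVAILABLE_REACTANTS")

  rec <- modify_session(s, c(A1 = 10))    # refill the missing reactant
  expect_gt(rec$a0, 0)
  run_until_break(s)                      # resumable until exhaustion again
  expect_equal(s$amounts[["A2"]], 11)

  # raising a kinetic constant scales the reaction weight linearly
  m2 <- make_fixture("CHAIN", n = 3)
  s2 <- debug_session(m2, seed = 3)
  bid <- add_breakpoint(s2, reaction = "R2")
  run_until_break(s2)
  w_before <- watch_record(s2)$weights[["R2"]]
  modify_session(s2, c(R2 = 5))           # k goes 1 -> 5
  w_after <- watch_record(s2)$weights[["R2"]]
  expect_equal(w_after, 5 * w_before)

  # empty edit map: snapshot unchanged
  rec0 <- watch_record(s2)
  rec1 <- modify_session(s2, stats::setNames(numeric(), character()))
  expect_equal(rec0$amounts, rec1$amounts)
  expect_equal(rec0$weights, rec1$weights)

  expect_error(modify_session(s2, c(A1 = -4)), "negative")
  expect_error(modify_session(s2, c(nonsuch = 1)), "unknown id")
})

test_that("skipping the pending instruction excludes it for one round", {
  # two competing consumers of A; break on R1, skip it, R2 must fire
  sp <- data.frame(id = c("A", "X", "Y"), name = c("A", "X", "Y"),
                   compartment = "cell", initial_amount = c(5, 0, 0),
                   boundary = FALSE, stringsAsFactors = FALSE)
  m <- new_model(sp, list(
    list(id = "R1", reactants = c(A = 1), products = c(X = 1),
         reversible = FALSE, kinetic_constant = 5),
    list(id = "R2", reactants = c(A = 1), products = c(Y = 1),
         reversible = FALSE, kinetic_constant = 1)))
  s <- debug_session(m, seed = 8)
  add_breakpoint(s, reaction = "R1")
  h <- run_until_break(s)
  expect_identical(s$pending$reaction, "R1")
  skip_instruction(s)
  h2 <- run_until_break(s, max_steps = 1)
  first <- s$events[[1]]$reaction
  expect_identical(first, "R2")
  # after that round R1 is eligible again
  expect_length(s$skip_once, 0L)

  # skipping the only available reaction deadlocks immediately
  m1 <- make_fixture("CHAIN", n = 2)
  s1 <- debug_session(m1, seed = 1)
  add_breakpoint(s1, reaction = "R1")
  run_until_break(s1)
  res <- skip_instruction(s1)
  expect_s3_class(res, "deadlock_report")
  expect_identical(res$reason, "NO_AVAILABLE_REACTANTS")

  # nothing pending: notice, state unchanged
  s3 <- debug_session(m1, seed = 1)
  expect_message(skip_instruction(s3), "nothing pending")
})

test_that("outlier breakpoints fire when the live run leaves the envelope", {
  m <- make_fixture("CHAIN", n = 2, k = 0.05)
  ens <- multi_simulate(m, n = 11, tmax = 20, seed = 40, watch = "A2")

  # a live member within the envelope at c=10 never breaks
  s <- debug_session(m, seed = 41, tmax = 20)
  outlier_breaks(s, ens, c = 10, species = "A2")
  h <- run_until_break(s)
  expect_false(h$status == "BREAK")

  # force the run far outside the envelope: the break fires on the next step
  s2 <- debug_session(m, seed = 41, tmax = 20)
  ids <- outlier_breaks(s2, ens, c = 3, species = "A2")
  run_until_break(s2, max_steps = 3)
  modify_session(s2, c(A2 = 5000))
  h2 <- run_until_break(s2)
  expect_identical(h2$status, "BREAK")
  expect_identical(h2$breakpoint, ids[[1]])
})
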