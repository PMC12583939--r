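test_that("a greedy walk follows the primary path on planned days", {
  g <- expand_implied_paths(example_fig1())
  w <- simulate_walk(g, walk_policy("greedy_primary"))
  expect_equal(w$status, "finished")
  expect_equal(w$trajectory$alias,
               c("IS", "V1", "V2", "V3", "V4", "V5", "V6", "IF"))
  expect_equal(w$trajectory$day[2:7], c(-28L, 0L, 6L, 13L, 20L, 27L))
  # determinism: identical trajectories for a repeated run
  w2 <- simulate_walk(g, walk_policy("greedy_primary"))
  expect_identical(w$trajectory, w2$trajectory)
})

test_that("only the forward unscheduled return is available", {
  g <- example_fig2b()
  # walk IS > V1 > V2 then detour to U
  w <- start_walk(g)
  for (al in c("V1", "V2", "U")) {
    avail <- available_transitions(g, w)
    tgt <- vapply(avail, function(e) node_alias_of(g, e$target), "")
    w <- step_walk(g, w, avail[[match(al, tgt)]])
  }
  avail <- available_transitions(g, w)
  tgt <- vapply(avail, function(e) node_alias_of(g, e$target), "")
  returns <- setdiff(tgt[grepl("^V", tgt)], character())
  expect_equal(returns, "V3")      # V3 allowed, V1/V2 visited, V4.. future
  expect_false("V2" %in% tgt)

  # with V3 already in the history, U -> V3 is unavailable
  w3 <- start_walk(g)
  for (al in c("V1", "V2", "V3", "U")) {
    avail <- available_transitions(g, w3)
    tgt <- vapply(avail, function(e) node_alias_of(g, e$target), "")
    w3 <- step_walk(g, w3, avail[[match(al, tgt)]])
  }
  tgt3 <- vapply(available_transitions(g, w3), function(e)
    node_alias_of(g, e$target), "")
  expect_false("V3" %in% tgt3)
  expect_true("V4" %in% tgt3)
})

test_that("withdrawal leaves only the exit route", {
  g <- example_fig2b()
  w <- start_walk(g)
  for (al in c("V1", "V2")) {
    avail <- available_transitions(g, w)
    tgt <- vapply(avail, function(e) node_alias_of(g, e$target), "")
    w <- step_walk(g, w, avail[[match(al, tgt)]])
  }
  w$flags$withdrawn <- TRUE
  avail <- available_transitions(g, w)
  tgt <- vapply(avail, function(e) node_alias_of(g, e$target), "")
  expect_equal(unique(tgt), "IF")
  w <- step_walk(g, w, avail[[1]])
  expect_equal(w$status, "withdrawn")
  # a finished walk offers nothing further
  expect_length(available_transitions(g, w), 0L)
})

test_that("stepping along an unavailable edge is refused", {
  g <- example_fig2b()
  w <- start_walk(g)
  v3 <- alias_id(g, "V3")
  far <- Filter(function(e) e$target == v3, g$edges)[[1]]
  expect_error(step_walk(g, w, far), "not currently available")
})

test_that("the repeat rule executes the blood-pressure activity four times", {
  bp <- example_bp_repeat()
  w <- simulate_walk(bp, walk_policy(prefer_loops = TRUE))
  expect_equal(w$status, "finished")
  expect_equal(unname(w$counts[["BP"]]), 4L)
  expect_equal(sum(w$trajectory$alias == "BP"), 4L)
})

test_that("the cycle-limit rule caps completed cycles at the stated maximum", {
  for (m in c(1L, 3L, 5L)) {
    g <- example_fig8_cycles(m)
    w <- simulate_walk(g, walk_policy(prefer_loops = TRUE))
    expect_equal(w$status, "finished")
    expect_equal(w$completed_cycles, m, label = paste("max", m))
  }
  # the degenerate template is linear: no cycle boundaries, no repeats
  g0 <- example_fig8_cycles(0L)
  w0 <- simulate_walk(g0, walk_policy(prefer_loops = TRUE))
  expect_equal(w0$completed_cycles, 0L)
  expect_false(any(soa_nodes(g0)$role %in% c("cycle_start", "cycle_finish")))
})

test_that("conditional activity selection exits a visit early", {
  g <- example_fig1()
  ag <- activity_graph(g, "V1")
  # criteria met: the full activity sequence runs
  ok <- simulate_walk(ag, walk_policy(flags = list(if_criteria_met = TRUE)))
  expect_equal(ok$status, "finished")
  expect_true("Vital signs" %in% ok$trajectory$alias)
  # criteria failed: early exit straight to the activity finish
  no <- simulate_walk(ag, walk_policy(flags = list(if_criteria_met = FALSE)))
  expect_equal(no$status, "finished")
  expect_false("Vital signs" %in% no$trajectory$alias)
  expect_equal(no$trajectory$alias[length(no$trajectory$alias)], "AF")
})

test_that("unscheduled insertion reproduces the planned/pushed timing cases", {
  g <- example_fig4()
  # a lone unscheduled visit between planned visits leaves the schedule alone
  w1 <- simulate_walk(g, walk_policy(unscheduled_days = 7L))
  cal1 <- walk_calendar(g, w1)
  expect_equal(cal1$day[cal1$alias == "U"], 7L)
  on <- !is.na(cal1$planned_day)
  expect_equal(cal1$day[on], cal1$planned_day[on])
  # colliding with a planned visit pushes it back one day
  w2 <- simulate_walk(g, walk_policy(unscheduled_days = c(7L, 26L, 27L)))
  cal2 <- walk_calendar(g, w2)
  expect_equal(cal2$day[cal2$alias == "V5"], 28L)
  expect_equal(cal2$protocol_day[cal2$alias == "V5"], "Day 29")
  expect_false(cal2$on_schedule[cal2$alias == "V5"])
})

test_that("random walks never take a backward unscheduled return", {
  g <- example_fig2b()
  for (s in 1:200) {
    w <- simulate_walk(g, walk_policy("random", max_steps = 100L), seed = s)
    traj <- w$trajectory$alias
    u_pos <- which(traj == "U")
    for (k in u_pos) {
      if (k == length(traj)) next
      nxt <- traj[k + 1L]
      if (grepl("^V", nxt))
        expect_false(nxt %in% traj[seq_len(k - 1L)],
                     label = paste("seed", s, "backward to", nxt))
    }
    # same seed reproduces the same trajectory
    if (s <= 3L)
      expect_identical(
        simulate_walk(g, walk_policy("random", max_steps = 100L), seed = s)$trajectory,
        w$trajectory)
  }
})

test_that("a rule deadlock is reported as a stall, not an error", {
  n <- list(soa_node("IS", role = "instantiation_start"),
            soa_node("V1", planned_timing = 0L, reference_timepoint = TRUE),
            soa_node("IF", role = "instantiation_finish"))
  e <- list(soa_transition("IS", "V1", delay = 0, primary_path = TRUE),
            soa_transition("V1", "IF", delay = 0, primary_path = TRUE,
                           rules = '{"consentObtained": true}'))
  g <- build_graph(n, e)
  w <- suppressWarnings(simulate_walk(g, walk_policy()))
  expect_equal(w$status, "stalled")
  expect_match(w$stall_message, "V1")
})

test_that("scripted walks follow the script then finish greedily", {
  g <- example_fig2b()
  w <- simulate_walk(g, walk_policy("scripted",
                                    script = c("V1", "V2", "U", "V3")))
  expect_equal(w$status, "finished")
  expect_equal(w$trajectory$alias[1:5], c("IS", "V1", "V2", "U", "V3"))
  expect_equal(w$trajectory$alias[length(w$trajectory$alias)], "IF")
  expect_error(walk_policy("scripted"), "script")
})
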