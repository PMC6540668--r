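cfg <- protocol_config()

as_log <- function(iv, id = "b1") {
  tibble::tibble(bee_id = id, circuit_index = seq_along(iv), interval_s = iv)
}

test_that("stoppage detection applies the >20 s rule with first-circuit discount", {
  seg <- detect_stoppages(as_log(c(1.0, 1.2, 25.0, 1.1)), cfg)
  expect_equal(seg$stoppage_indices, 3L)

  # an over-threshold first circuit is an acclimatisation stall, not a stoppage
  seg <- detect_stoppages(as_log(c(30.0, 1.0, 1.0)), cfg)
  expect_equal(seg$stoppage_indices, integer(0))

  # a tie at exactly the threshold is not a stoppage
  seg <- detect_stoppages(as_log(c(1, 20.0, 1)), cfg)
  expect_equal(seg$stoppage_indices, integer(0))

  # empty log: did not fly
  empty <- as_log(numeric(0))
  seg <- detect_stoppages(empty, cfg)
  expect_false(seg$flew)
  expect_equal(seg$n_in_test, 0L)
})

test_that("the session ends at the stoppage budget or the cap, whichever first", {
  # 6th genuine stoppage terminates the test on that circuit
  iv <- rep(1, 40)
  iv[c(5, 10, 15, 20, 25, 30)] <- 21
  seg <- detect_stoppages(as_log(iv), cfg)
  expect_equal(seg$n_in_test, 30L)
  expect_equal(seg$stoppage_indices, c(5L, 10L, 15L, 20L, 25L))
  expect_equal(seg$terminated_by, "stoppage_budget")

  # cap reached mid-log: the straddling circuit is retained, later ones dropped
  iv <- c(rep(1000, 3), 700, 5, 5)
  seg <- detect_stoppages(as_log(iv), cfg)
  expect_equal(seg$n_in_test, 4L)
  expect_equal(seg$terminated_by, "session_cap")
  m <- compute_metrics(as_log(iv), clean_circuits(as_log(iv), seg, cfg), cfg)
  expect_true(m$completed_cap)
  expect_equal(m$total_duration_s, 3700)
})

test_that("circuit cleaning excludes start, stoppage neighbourhoods, unioned and clipped", {
  iv <- rep(1, 20); iv[10] <- 25
  log <- as_log(iv)
  seg <- clean_circuits(log, detect_stoppages(log, cfg), cfg)
  expect_equal(seg$excluded_indices,
               as.integer(c(1:5, 9:15)))

  iv <- rep(1, 10)
  log <- as_log(iv)
  seg <- clean_circuits(log, detect_stoppages(log, cfg), cfg)
  expect_equal(seg$excluded_indices, 1:5)

  # a stoppage at the very end clips its trailing window
  iv <- rep(1, 8); iv[8] <- 30
  log <- as_log(iv)
  seg <- clean_circuits(log, detect_stoppages(log, cfg), cfg)
  expect_equal(seg$excluded_indices, as.integer(c(1:5, 7, 8)))
})

test_that("metrics follow the protocol formulas on known sessions", {
  # the 100 m inclusion threshold sits at 118 circuits
  log <- as_log(rep(1, 118))
  m <- process_session(log, cfg)
  expect_equal(m$total_distance_m, 118 * 0.848, tolerance = 1e-12)
  expect_equal(m$total_distance_m, 100.064)
  expect_true(m$over_100m)

  # constant 1 s circuits: every velocity equals the circumference
  expect_equal(m$mean_velocity_mps, 0.848)
  expect_equal(m$max_velocity_mps, 0.848)
  expect_true(all(m$per_circuit[[1]]$velocity_mps == 0.848))

  # 117 circuits just misses the threshold
  m117 <- process_session(as_log(rep(1, 117)), cfg)
  expect_false(m117$over_100m)

  # velocity fields are NA when cleaning leaves nothing, endurance still real
  m3 <- process_session(as_log(rep(2, 3)), cfg)
  expect_true(is.na(m3$mean_velocity_mps))
  expect_equal(m3$total_duration_s, 6)
  expect_equal(m3$total_distance_m, 3 * 0.848)
})

test_that("velocity binning yields 18 window means keyed to original indices", {
  # 900 cleaned circuits -> all 18 bins filled
  pc <- tibble::tibble(circuit_index = 1:900, velocity_mps = rep(0.7, 900))
  b <- bin_velocity(pc, cfg)
  expect_equal(nrow(b), 18)
  expect_equal(sum(!is.na(b$mean_velocity_mps)), 18)
  expect_equal(b$mean_velocity_mps, rep(0.7, 18), tolerance = 1e-12)

  # gaps map to NA bins; circuits beyond the window are ignored
  pc <- tibble::tibble(circuit_index = c(1:40, 101:120, 880:950),
                       velocity_mps = 1)
  b <- bin_velocity(pc, cfg)
  expect_true(is.na(b$mean_velocity_mps[2]))
  expect_equal(b$n_circuits[1], 40L)
  expect_equal(b$n_circuits[3], 20L)
  expect_equal(b$n_circuits[18], 21L)  # 880..900 only

  # full-bin decomposition: mean of bin means equals the overall mean
  set.seed(99)
  pc <- tibble::tibble(circuit_index = 1:900,
                       velocity_mps = stats::runif(900, 0.3, 1.5))
  b <- bin_velocity(pc, cfg)
  expect_equal(mean(b$mean_velocity_mps), mean(pc$velocity_mps),
               tolerance = 1e-9)
})

test_that("circuit-count arithmetic inverts distance correctly", {
  expect_identical(circuits_for_distance(100, 0.848), 118L)
  expect_identical(circuits_for_distance(0.848, 0.848), 1L)
  # linear-search oracle at an arbitrary target
  target <- 760
  n <- 1L
  while (n * 0.848 < target) n <- n + 1L
  expect_identical(circuits_for_distance(760, 0.848), n)
  expect_identical(n, 897L)
  expect_error(circuits_for_distance(-1, 0.848), "positive")
  expect_error(circuits_for_distance(100, 0), "positive")
})

test_that("session processing agrees with brute-force scans on random sessions", {
  set.seed(2024)
  for (i in 1:300) {
    n <- sample(1:400, 1)
    iv <- random_intervals(n)
    log <- as_log(iv)
    seg <- detect_stoppages(log, cfg)
    ora <- oracle_stoppages(iv, cfg)
    expect_identical(seg$stoppage_indices, as.integer(ora$stoppages))
    expect_identical(seg$n_in_test, as.integer(ora$n_in_test))

    seg <- clean_circuits(log, seg, cfg)
    expect_identical(seg$excluded_indices,
                     as.integer(oracle_exclusions(ora$n_in_test,
                                                  ora$stoppages, cfg)))

    m <- compute_metrics(log, seg, cfg)
    om <- oracle_metrics(iv, ora$n_in_test, seg$excluded_indices, cfg)
    expect_equal(m$total_distance_m, om$total_distance_m)
    expect_equal(m$total_duration_s, om$total_duration_s)
    expect_equal(m$mean_velocity_mps, om$mean_velocity_mps, tolerance = 1e-12)
    expect_equal(m$max_velocity_mps, om$max_velocity_mps, tolerance = 1e-12)

    expect_equal(m$binned[[1]]$mean_velocity_mps,
                 oracle_bins(m$per_circuit[[1]], cfg), tolerance = 1e-12)
  }
})

test_that("session invariants hold across random sessions", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(2:300, 1)
    iv <- random_intervals(n)
    m <- process_session(as_log(iv), cfg)
    # conservation: distance decomposes into an integer circuit count
    expect_equal(m$total_distance_m / cfg$circumference_m, m$n_circuits,
                 tolerance = 1e-9)
    # exclusion bound: at most 5 start circuits plus 7 per stoppage
    seg <- clean_circuits(as_log(iv), detect_stoppages(as_log(iv), cfg), cfg)
    expect_lte(length(seg$excluded_indices),
               cfg$post_start_exclusion + 7 * length(seg$stoppage_indices))
    # mean velocity is bracketed by the cleaned extremes
    if (!is.na(m$mean_velocity_mps)) {
      pc <- m$per_circuit[[1]]$velocity_mps
      expect_gte(m$mean_velocity_mps, min(pc) - 1e-12)
      expect_lte(m$mean_velocity_mps, max(pc) + 1e-12)
    }
    # monotonicity: extending the session never shrinks distance or duration
    iv2 <- c(iv, stats::runif(5, 0.5, 2))
    m2 <- process_session(as_log(iv2), cfg)
    expect_gte(m2$total_distance_m, m$total_distance_m)
    expect_gte(m2$total_duration_s, m$total_duration_s)
  }
})
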