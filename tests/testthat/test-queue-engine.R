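test_that("queue_step reproduces hand-traced FCFS assignments", {
  one <- queue_step(0, 5, 1)
  expect_equal(one$start, 0)
  expect_equal(one$departure, 5)
  expect_equal(one$wait, 0)

  res <- queue_step(c(0, 1, 2), c(10, 10, 10), 2)
  expect_equal(res$start, c(0, 1, 10))
  expect_equal(res$departure, c(10, 11, 20))
  expect_equal(res$wait, c(0, 0, 8))

  idle <- queue_step(c(0, 0, 0), c(1, 2, 3), 3)
  expect_equal(idle$wait, c(0, 0, 0))
  # ties broken by lowest server index
  expect_equal(idle$server, c(1, 2, 3))

  empty <- queue_step(numeric(0), numeric(0), 2)
  expect_equal(nrow(empty), 0)
})

test_that("queue_step rejects contract violations", {
  expect_error(queue_step(c(2, 1), c(1, 1), 1), class = "vaxflow_contract_error")
  expect_error(queue_step(c(0, 1), c(1, 1, 1), 1), class = "vaxflow_contract_error")
  expect_error(queue_step(c(0, 1), c(1, -1), 1), class = "vaxflow_contract_error")
  expect_error(queue_step(0, 1, 0), class = "vaxflow_domain_error")
})

test_that("queue_step matches the event-driven oracle on random instances", {
  set.seed(501)
  for (r in 1:300) {
    n <- sample(1:50, 1)
    c_srv <- sample(1:5, 1)
    arr <- sort(round(cumsum(rexp(n, 1)), 3))
    serv <- round(rexp(n, 0.5), 3)
    got <- queue_step(arr, serv, c_srv)
    want <- oracle_queue(arr, serv, c_srv)
    expect_equal(got$start, want$start)
    expect_equal(got$departure, want$departure)
  }
})

test_that("adding servers never delays any service start", {
  set.seed(502)
  for (r in 1:50) {
    n <- sample(2:40, 1)
    arr <- sort(runif(n, 0, 60))
    serv <- rexp(n, 0.3)
    prev <- queue_step(arr, serv, 1)$start
    for (c_srv in 2:4) {
      cur <- queue_step(arr, serv, c_srv)$start
      expect_true(all(cur <= prev + 1e-12))
      prev <- cur
    }
  }
})

test_that("queue invariants hold on a congested instance", {
  set.seed(503)
  arr <- sort(runif(200, 0, 100))
  serv <- rexp(200, 0.5)
  res <- queue_step(arr, serv, 3)
  expect_true(all(res$arrival <= res$start))
  expect_true(all(res$start <= res$departure))
  expect_equal(res$departure, res$start + serv)
  # no server serves two customers at overlapping times
  for (s in unique(res$server)) {
    rows <- res[res$server == s, ]
    rows <- rows[order(rows$start), ]
    expect_true(all(utils::head(rows$departure, -1) <= utils::tail(rows$start, -1) + 1e-12))
  }
})

test_that("lags shift times by independent non-negative draws", {
  times <- c(5, 1, 9, 3)
  expect_equal(apply_lag(times, det_dist(0)), times)
  expect_equal(apply_lag(times, det_dist(1.5)), times + 1.5)
  set.seed(504)
  n <- 1e5
  shifted <- apply_lag(rep(0, n), dist_spec("uniform", min = 0.5, max = 2))
  expect_true(all(shifted >= 0.5 & shifted <= 2))
  se <- (1.5 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(shifted) - 1.25), 3 * se)
  expect_error(apply_lag(c(1, Inf), det_dist(1)), class = "vaxflow_contract_error")
})

test_that("fork_join pairs patients with doses first-come-first-served", {
  expect_equal(fork_join(c(10, 12), c(0, 0, 0)), c(10, 12))
  expect_equal(fork_join(c(10, 12), c(11, 11)), c(11, 12))
  out <- fork_join(sort(runif(20, 0, 10)), sort(runif(30, 0, 10)))
  expect_true(all(diff(out) >= 0))
  expect_error(fork_join(5, numeric(0)), class = "vaxflow_infeasible_error")
  expect_error(
    fork_join(c(3, 1), c(0, 0)),
    class = "vaxflow_contract_error"
  )
})

test_that("an uncontested patient's processing time is the sum of services and lags", {
  net <- deterministic_gp_network(
    reg = 3.7, vac = 6.3, obs = 20,
    walk_lag = det_dist(1.5)
  )
  log <- simulate_network(net, manual_arrivals(10), numeric(10))
  expect_equal(nrow(log), 1)
  expect_equal(log$processing_time, 3.7 + 6.3 + 20 + 2 * 1.5)
  expect_equal(log$registration_start - log$registration_arrival, 0)
  expect_equal(log$vaccination_start - log$vaccination_arrival, 0)
})

test_that("a deterministic two-patient single-server network matches a hand trace", {
  net <- deterministic_gp_network(
    reg = 4, vac = 6, obs = 10,
    n_reg = 1, n_vac = 1, seats = 1, prep = 1, n_prep = 1
  )
  log <- simulate_network(net, manual_arrivals(c(0, 1)), c(0, 0))
  log <- log[order(log$patient_id), ]
  # registration: starts 0 and 4; vaccination: starts 4 and 10
  expect_equal(log$registration_start, c(0, 4))
  expect_equal(log$vaccination_arrival, c(4, 8))
  expect_equal(log$vaccination_start, c(4, 10))
  # single observation seat: second patient waits for the seat
  expect_equal(log$observation_start, c(10, 20))
  expect_equal(log$processing_time, c(20, 29))
})

test_that("dose shortages at the join are reported, and doses can throttle", {
  net <- deterministic_gp_network()
  expect_error(
    simulate_network(net, manual_arrivals(c(0, 5)), numeric(1)),
    class = "vaxflow_infeasible_error"
  )
  # a single slow-prep dose delays vaccination via the join
  slow <- deterministic_gp_network(prep = 30, n_prep = 1)
  log <- simulate_network(slow, manual_arrivals(0), 0)
  expect_equal(log$vaccination_arrival, 30) # dose ready at t = 30
})

test_that("every attended patient appears exactly once in the log", {
  sch <- build_schedule("gp", "medium")
  net <- make_gp_network("medium")
  set.seed(505)
  arr <- generate_arrivals(sch)
  log <- simulate_network(net, arr, generate_dose_demand(sch))
  expect_equal(nrow(log), sum(arr$attended))
  expect_equal(sort(log$patient_id), sort(arr$patient_id[arr$attended]))
  # timestamps non-decreasing along each patient's path
  cols <- c(
    "arrival_time", "registration_arrival", "registration_start",
    "registration_depart", "vaccination_arrival", "vaccination_start",
    "vaccination_depart", "observation_arrival", "observation_start",
    "observation_depart"
  )
  mat <- as.matrix(log[, cols])
  expect_true(all(mat[, -1] - mat[, -ncol(mat)] >= -1e-9))
})
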