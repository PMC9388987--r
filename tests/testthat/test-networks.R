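test_that("hub networks carry the published staffing and seats", {
  low <- make_hub_network("low")
  expect_equal(total_staff(low), 21)
  obs_low <- low$stations[[length(low$stations)]]
  expect_equal(obs_low$n_servers, 25)
  expect_equal(
    tidy(low)$station,
    c(
      "preparation", "entrance", "registration", "assessment",
      "vaccination", "observation"
    )
  )

  high <- make_hub_network("high")
  expect_equal(total_staff(high), 63)
  expect_equal(tidy(high)$n_servers[tidy(high)$station == "vaccination"], 15)
  expect_equal(tidy(high)$n_servers[tidy(high)$station == "observation"], 75)

  med <- tidy(make_hub_network("medium"))
  expect_equal(total_staff(make_hub_network("medium")), 42)
  # three registration staff for every preparation staff member
  expect_equal(
    med$n_servers[med$station == "registration"],
    3 * med$n_servers[med$station == "preparation"]
  )
  expect_error(make_hub_network("maximal"), class = "vaxflow_config_error")
})

test_that("GP networks carry the published staffing and seats", {
  low <- make_gp_network("low")
  expect_equal(total_staff(low), 4)
  expect_equal(tidy(low)$n_servers[tidy(low)$station == "observation"], 5)
  expect_equal(
    tidy(low)$station,
    c("preparation", "registration", "vaccination", "observation")
  )
  expect_null(low$walk_lag) # walking time negligible at a GP clinic

  high <- make_gp_network("high")
  expect_equal(total_staff(high), 12)
  expect_equal(tidy(high)$n_servers[tidy(high)$station == "vaccination"], 6)

  # medium doubles low at every station
  expect_equal(
    tidy(make_gp_network("medium"))$n_servers,
    2 * tidy(low)$n_servers
  )
})

test_that("staff ratios across stations are level-invariant", {
  for (maker in list(make_hub_network, make_gp_network)) {
    shares <- sapply(c("low", "medium", "high"), function(lev) {
      net <- maker(lev)
      counts <- tidy(net)
      counts <- counts$n_servers[counts$role == "staff"]
      counts / sum(counts)
    })
    expect_equal(shares[, "medium"], shares[, "low"])
    expect_equal(shares[, "high"], shares[, "low"])
  }
})

test_that("staffing overrides merge into level defaults", {
  net <- make_hub_network("low", staffing = c(vaccination = 7))
  counts <- tidy(net)
  expect_equal(counts$n_servers[counts$station == "vaccination"], 7)
  expect_equal(counts$n_servers[counts$station == "entrance"], 4)
  expect_error(
    make_hub_network("low", staffing = c(pharmacy = 2)),
    class = "vaxflow_config_error"
  )
  expect_error(
    make_gp_network("low", staffing = c(vaccination = 0)),
    class = "vaxflow_config_error"
  )
})

test_that("staff reduction cycles largest stations first and keeps floors", {
  hub_low <- make_hub_network("low") # (2, 4, 6, 4, 5)
  expect_equal(
    vaxflow:::staff_counts(reduce_staff(hub_low, 0)),
    vaxflow:::staff_counts(hub_low)
  )
  reduced <- reduce_staff(hub_low, 3)
  expect_equal(
    unname(vaxflow:::staff_counts(reduced)),
    c(2, 4, 5, 3, 4)
  )
  # totals drop by exactly k and no station hits zero, as far as feasible
  for (k in 1:16) {
    r <- reduce_staff(hub_low, k)
    counts <- vaxflow:::staff_counts(r)
    expect_equal(sum(counts), 21 - k)
    expect_true(all(counts >= 1))
  }
  expect_error(
    reduce_staff(make_gp_network("low"), 3), # (1,1,2): only 1 removable
    class = "vaxflow_infeasible_error"
  )
  expect_error(reduce_staff(hub_low, 21), class = "vaxflow_domain_error")
  expect_error(reduce_staff(hub_low, -1), class = "vaxflow_domain_error")
})

test_that("custom networks validate their pieces", {
  expect_error(
    vax_network("x", list(), vax_station("preparation", 1, det_dist(1))),
    class = "vaxflow_config_error"
  )
  expect_error(
    vax_station("vaccination", 0, det_dist(1)),
    class = "vaxflow_config_error"
  )
  net <- vax_network(
    "custom",
    stations = list(vax_station("vaccination", 2, det_dist(5))),
    prep = vax_station("preparation", 1, det_dist(1))
  )
  expect_s3_class(net, "vax_network")
  expect_equal(total_staff(net), 3)
})
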