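# Shared fixture builders.

det_dist <- function(value) dist_spec("deterministic", value = value)

# Single-station network with a deterministic service, no prep pressure.
single_station_network <- function(n_servers, service_minutes,
                                   prep_servers = 1) {
  vax_network(
    site = "test",
    stations = list(
      vax_station("observation", n_servers,
        obs_mixture(
          main = det_dist(service_minutes),
          adverse = det_dist(service_minutes),
          adverse_prob = 0
        ),
        role = "seats"
      )
    ),
    prep = vax_station("preparation", prep_servers, det_dist(0))
  )
}

# GP-shaped network with fully deterministic services (and optional lag).
deterministic_gp_network <- function(reg = 3.7, vac = 6.3, obs = 20,
                                     n_reg = 5, n_vac = 5, seats = 50,
                                     prep = 0.1, n_prep = 5,
                                     walk_lag = NULL) {
  vax_network(
    site = "test",
    stations = list(
      vax_station("registration", n_reg, det_dist(reg)),
      vax_station("vaccination", n_vac, det_dist(vac)),
      vax_station("observation", seats,
        obs_mixture(main = det_dist(obs), adverse = det_dist(obs), adverse_prob = 0),
        role = "seats"
      )
    ),
    prep = vax_station("preparation", n_prep, det_dist(prep)),
    walk_lag = walk_lag
  )
}

# Arrivals object for explicit arrival times (all attended).
manual_arrivals <- function(times) {
  sch <- build_schedule("gp", bookings_per_slot = 0)
  out <- tibble::tibble(
    patient_id = seq_along(times),
    slot_time = 0,
    arrival_time = sort(times),
    attended = rep(TRUE, length(times))
  )
  structure(out,
    site = "test",
    class = c("vax_arrivals", class(out))
  )
}

# The published shifted-exponential service specs and Table 1's printed
# one-decimal percentile cells (5/25/50/75/95%).
table1_exponential_rows <- function() {
  list(
    list(
      spec = dist_spec("exponential", shift = 1, rate = 3),
      printed = list(
        hub_preparation = c(1.0, 1.1, 1.2, 1.5, 2.0),
        gp_preparation = c(1.0, 1.1, 1.2, 1.4, 1.9)
      )
    ),
    list(
      spec = dist_spec("exponential", shift = 2, rate = 1),
      printed = list(
        hub_entrance = c(2.0, 2.3, 2.7, 3.2, 4.8),
        hub_assessment = c(2.1, 2.3, 2.7, 3.4, 4.9)
      )
    ),
    list(
      spec = dist_spec("exponential", shift = 3, rate = 0.7),
      printed = list(hub_registration = c(3.1, 3.4, 4.0, 5.0, 7.3))
    ),
    list(
      spec = dist_spec("exponential", shift = 3, rate = 1),
      printed = list(
        hub_vaccination = c(3.1, 3.3, 3.7, 4.3, 5.8),
        gp_registration = c(3.1, 3.3, 3.7, 4.3, 5.9)
      )
    ),
    list(
      spec = dist_spec("exponential", shift = 5, rate = 0.5),
      printed = list(gp_vaccination = c(5.1, 5.6, 6.3, 7.7, 11.2))
    ),
    list(
      spec = dist_spec("exponential", shift = 20, rate = 0.1),
      printed = list(
        hub_adverse = c(20.4, 22.9, 26.7, 33.0, 46.1),
        gp_adverse = c(20.4, 22.6, 26.6, 33.3, 48.7)
      )
    )
  )
}

table1_percentiles <- c(0.05, 0.25, 0.5, 0.75, 0.95)
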