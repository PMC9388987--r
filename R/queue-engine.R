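#' Multi-server first-come-first-served queue assignment
#'
#' The core queue computation. Customers are taken in arrival order and each
#' is assigned to the server that becomes free earliest (ties broken by
#' lowest server index); service starts at the later of the customer's
#' arrival and that server's free time. This vectors-in, vectors-out
#' assignment is equivalent to a discrete-event FCFS simulation but avoids
#' an event calendar entirely.
#'
#' @param arrival_times Numeric vector, sorted non-decreasing.
#' @param service_times Numeric vector of the same length, all `>= 0`.
#' @param n_servers Number of identical parallel servers (`>= 1`).
#' @return A tibble with one row per customer, in arrival order: `arrival`,
#'   `start`, `departure`, `server`, `wait` (`= start - arrival`).
#'   Deterministic given its inputs.
#' @examples
#' queue_step(c(0, 1, 2), c(10, 10, 10), n_servers = 2)
#' @export
queue_step <- function(arrival_times, service_times, n_servers) {
  if (!is.numeric(arrival_times) || anyNA(arrival_times)) {
    abort_contract("`arrival_times` must be numeric without missing values.")
  }
  if (!is_nondecreasing(arrival_times)) {
    abort_contract("`arrival_times` must be sorted non-decreasing.")
  }
  if (length(service_times) != length(arrival_times)) {
    abort_contract(
      "`service_times` must have the same length as `arrival_times`."
    )
  }
  if (anyNA(service_times) || any(service_times < 0)) {
    abort_contract("`service_times` must be non-negative.")
  }
  if (!is_count(n_servers, min = 1)) {
    abort_domain("`n_servers` must be an integer >= 1.")
  }
  n <- length(arrival_times)
  free <- numeric(n_servers)
  start <- numeric(n)
  depart <- numeric(n)
  server <- integer(n)
  for (i in seq_len(n)) {
    s <- which.min(free) # first minimum = lowest server index on ties
    st <- max(arrival_times[i], free[s])
    start[i] <- st
    depart[i] <- st + service_times[i]
    server[i] <- s
    free[s] <- depart[i]
  }
  tibble(
    arrival = as.numeric(arrival_times),
    start = start,
    departure = depart,
    server = server,
    wait = start - arrival_times
  )
}

#' Apply a serverless inter-station lag
#'
#' Lags (walking time between stations) consume time but no server. Each
#' time receives an independent non-negative draw from `lag`. Because draws
#' are independent, patients can overtake one another in transit; callers
#' re-rank patients by post-lag ready time before the next FCFS station.
#'
#' @param times Numeric vector of departure times.
#' @param lag A [dist_spec()]; draws below zero are rejected and resampled.
#' @return `times + lag draws`, same order as the input.
#' @export
apply_lag <- function(times, lag) {
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times))) {
    abort_contract("`times` must be finite numeric values.")
  }
  times + sample_service_times(lag, length(times))
}

#' Join a patient queue with a prepared-resource queue
#'
#' Realises the fork/join of the dose-preparation queue with the patient
#' queue at the vaccination station: the i-th patient (in ready order)
#' consumes the i-th completed dose, and becomes available for vaccination
#' at the later of the two times.
#'
#' @param patient_ready Sorted vector of n patient ready times.
#' @param resource_ready Sorted vector of m >= n resource-completion times.
#' @return Effective arrival vector `pmax(patient_ready, resource_ready[1:n])`,
#'   sorted non-decreasing.
#' @export
fork_join <- function(patient_ready, resource_ready) {
  if (!is_nondecreasing(patient_ready) || !is_nondecreasing(resource_ready)) {
    abort_contract(
      "`patient_ready` and `resource_ready` must be sorted non-decreasing."
    )
  }
  n <- length(patient_ready)
  m <- length(resource_ready)
  if (m < n) {
    abort_infeasible(paste0(
      "Insufficient doses at the join: ", n, " patients but only ", m,
      " doses prepared (short by ", n - m, ")."
    ))
  }
  pmax(patient_ready, resource_ready[seq_len(n)])
}

#' Simulate one clinic day through a queue network
#'
#' Chains [queue_step()] through the network's ordered stations. For hub
#' networks a walking lag is inserted between consecutive stations (patients
#' are re-ranked by post-lag ready time before each station, since FCFS
#' applies on station-arrival order). The dose-preparation queue runs in
#' parallel on `dose_releases` and joins the patient queue at the
#' vaccination station via [fork_join()]. The observation stage is a
#' [queue_step()] whose "servers" are seats; observation durations come
#' from the network's bimodal mixture and set each patient's adverse flag.
#' All attended patients are processed to completion, including past the
#' nominal closing time (overtime).
#'
#' @param network A [make_hub_network()] / [make_gp_network()] result.
#' @param arrivals A [generate_arrivals()] result (no-shows are dropped).
#' @param dose_releases Release times from [generate_dose_demand()].
#' @return A tibble of class `vax_log`, one row per attended patient:
#'   `patient_id`, `slot_time`, `arrival_time`, `adverse`, then
#'   `<station>_arrival` / `_start` / `_depart` for every station, and
#'   `processing_time` (first-station arrival to observation exit).
#'   Attributes: `stations` (layout summary), `dose_log` (the preparation
#'   queue's own log), `wastage` (doses prepared minus patients served) and
#'   `site`.
#' @export
simulate_network <- function(network, arrivals, dose_releases) {
  if (!inherits(network, "vax_network")) {
    abort_config("`network` must be a `vax_network`.")
  }
  if (!inherits(arrivals, "vax_arrivals")) {
    abort_config("`arrivals` must come from `generate_arrivals()`.")
  }
  att <- dplyr::filter(arrivals, .data$attended)
  att <- dplyr::arrange(att, .data$arrival_time, .data$patient_id)
  n <- nrow(att)

  # dose preparation runs in parallel, fed by slot-release times
  dose_releases <- sort(dose_releases)
  prep_serv <- sample_service_times(network$prep$service, length(dose_releases))
  prep_q <- queue_step(dose_releases, prep_serv, network$prep$n_servers)
  dose_ready <- sort(prep_q$departure)

  st_names <- vapply(network$stations, function(s) s$name, character(1))
  log <- tibble(
    patient_id = att$patient_id,
    slot_time = att$slot_time,
    arrival_time = att$arrival_time,
    adverse = rep(NA, n)
  )
  for (nm in st_names) {
    log[[paste0(nm, "_arrival")]] <- rep(NA_real_, n)
    log[[paste0(nm, "_start")]] <- rep(NA_real_, n)
    log[[paste0(nm, "_depart")]] <- rep(NA_real_, n)
  }

  idx <- seq_len(n) # row indices of log, in current queue order
  t <- att$arrival_time
  first <- TRUE
  for (st in network$stations) {
    if (!first && !is.null(network$walk_lag)) {
      t <- apply_lag(t, network$walk_lag)
    }
    if (!first) {
      o <- order(t)
      idx <- idx[o]
      t <- t[o]
    }
    first <- FALSE
    if (identical(st$name, "vaccination")) {
      t <- fork_join(t, dose_ready)
    }
    if (inherits(st$service, "vax_mixture")) {
      obs <- sample_observation(st$service, n)
      serv <- obs$duration
      log$adverse[idx] <- obs$adverse
    } else {
      serv <- sample_service_times(st$service, n)
    }
    res <- queue_step(t, serv, st$n_servers)
    log[[paste0(st$name, "_arrival")]][idx] <- res$arrival
    log[[paste0(st$name, "_start")]][idx] <- res$start
    log[[paste0(st$name, "_depart")]][idx] <- res$departure
    t <- res$departure
  }

  last <- st_names[length(st_names)]
  log$processing_time <- log[[paste0(last, "_depart")]] - log$arrival_time

  station_tbl <- tibble(
    name = c(network$prep$name, st_names),
    n_servers = c(
      network$prep$n_servers,
      vapply(network$stations, function(s) s$n_servers, numeric(1))
    ),
    role = c(
      network$prep$role,
      vapply(network$stations, function(s) s$role, character(1))
    )
  )
  structure(log,
    stations = station_tbl,
    dose_log = prep_q,
    wastage = length(dose_releases) - n,
    site = network$site,
    class = c("vax_log", setdiff(class(log), "vax_log"))
  )
}
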