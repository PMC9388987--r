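#' Per-patient total processing times
#'
#' Processing time is the total time from arrival at the first station to
#' departure from the observation area, in minutes.
#'
#' @param log A `vax_log` from [simulate_network()].
#' @return Numeric vector, one value per attended patient.
#' @export
processing_times <- function(log) {
  if (!inherits(log, "vax_log")) {
    abort_config("`log` must be a `vax_log` from `simulate_network()`.")
  }
  x <- log$processing_time
  if (anyNA(x)) {
    abort_contract("Patient log is incomplete: missing processing times.")
  }
  x
}

#' Daily throughput
#'
#' Number of patients completing the whole network (departing observation)
#' in the simulated clinic day. Equals attended bookings, since every
#' attended patient is processed to completion (overtime permitted).
#'
#' @param log A `vax_log`.
#' @return Integer count.
#' @export
throughput <- function(log) {
  if (!inherits(log, "vax_log")) {
    abort_config("`log` must be a `vax_log` from `simulate_network()`.")
  }
  stations <- attr(log, "stations")
  last <- stations$name[nrow(stations)]
  sum(!is.na(log[[paste0(last, "_depart")]]))
}

#' Per-station utilisation
#'
#' Staff utilisation is the average proportion of a station's servers that
#' are busy serving a patient across the simulation run:
#' `sum(depart - start) / (n_servers * horizon)`. The horizon is the span
#' of the simulation run — from the first arrival into the system to the
#' last departure out of it (including any end-of-day overtime) — and is
#' shared by every station, so stations early and late in the chain are
#' measured against the same clock. The preparation queue is measured from
#' its own dose log over the same horizon; the observation row reports seat
#' occupancy rather than staff utilisation (`role = "seats"`).
#'
#' @param log A `vax_log` from [simulate_network()].
#' @return A tibble with columns `station`, `role`, `n_servers`,
#'   `utilisation`.
#' @export
staff_utilisation <- function(log) {
  if (!inherits(log, "vax_log")) {
    abort_config("`log` must be a `vax_log` from `simulate_network()`.")
  }
  stations <- attr(log, "stations")
  dose_log <- attr(log, "dose_log")
  patient_stations <- stations$name[stations$name != "preparation"]
  last <- patient_stations[length(patient_stations)]
  span_start <- suppressWarnings(min(
    log$arrival_time, dose_log$arrival,
    Inf
  ))
  span_end <- suppressWarnings(max(
    log[[paste0(last, "_depart")]], dose_log$departure,
    -Inf
  ))
  horizon <- span_end - span_start
  util <- vapply(seq_len(nrow(stations)), function(i) {
    nm <- stations$name[i]
    if (nm == "preparation") {
      st <- dose_log$start
      dep <- dose_log$departure
    } else {
      st <- log[[paste0(nm, "_start")]]
      dep <- log[[paste0(nm, "_depart")]]
    }
    busy <- sum(dep - st)
    if (!is.finite(horizon) || horizon <= 0) {
      if (busy > 0) {
        abort_contract(paste0(
          "Station '", nm, "' delivered service over a zero-length horizon."
        ))
      }
      return(0)
    }
    busy / (stations$n_servers[i] * horizon)
  }, numeric(1))
  tibble(
    station = stations$name,
    role = stations$role,
    n_servers = stations$n_servers,
    utilisation = util
  )
}

# One replication's summary: pooled later by summarize_reps().
summarize_log <- function(log, rep = 1L, seed = NA_integer_) {
  times <- processing_times(log)
  list(
    rep = rep,
    seed = seed,
    times = times,
    throughput = throughput(log),
    wastage = attr(log, "wastage"),
    util = staff_utilisation(log)
  )
}

#' Pool replication summaries
#'
#' Pools patient-level processing times across replications by
#' concatenation before taking percentiles (replications share an identical
#' design, so this matches averaging quantiles up to Monte-Carlo noise),
#' and reports per-replication spread for each metric. Percentiles use the
#' median-unbiased sample-quantile convention (type 8).
#'
#' @param summaries A non-empty list of per-replication summaries as
#'   produced internally by [run_baseline()] (each holding patient times,
#'   throughput, wastage and per-station utilisation).
#' @return A list of class `vax_summary`: `pooled` (one-row tibble),
#'   `per_rep` (one row per replication), `util` (per-station mean and max
#'   utilisation across replications) and `times` (pooled patient-level
#'   processing times).
#' @export
summarize_reps <- function(summaries) {
  if (!is.list(summaries) || length(summaries) == 0) {
    abort_domain("`summaries` must be a non-empty list of replications.")
  }
  per_rep <- purrr::map(summaries, function(s) {
    staff_util <- s$util$utilisation[s$util$role == "staff"]
    tibble(
      rep = s$rep,
      seed = s$seed,
      patients = length(s$times),
      median = if (length(s$times)) pct(s$times, 0.5) else NA_real_,
      p95 = if (length(s$times)) pct(s$times, 0.95) else NA_real_,
      mean = if (length(s$times)) mean(s$times) else NA_real_,
      throughput = s$throughput,
      wastage = s$wastage,
      max_staff_util = if (length(staff_util)) max(staff_util) else NA_real_
    )
  })
  per_rep <- purrr::list_rbind(per_rep)
  times <- unlist(purrr::map(summaries, "times"), use.names = FALSE)
  util <- purrr::list_rbind(
    purrr::imap(summaries, function(s, i) {
      dplyr::mutate(s$util, rep = per_rep$rep[i])
    })
  )
  util_pooled <- dplyr::summarise(
    dplyr::group_by(util, .data$station, .data$role, .data$n_servers),
    mean_utilisation = mean(.data$utilisation),
    max_utilisation = max(.data$utilisation),
    .groups = "drop"
  )
  staff_mean <- util_pooled$mean_utilisation[util_pooled$role == "staff"]
  pooled <- tibble(
    reps = nrow(per_rep),
    patients = length(times),
    median = if (length(times)) pct(times, 0.5) else NA_real_,
    p95 = if (length(times)) pct(times, 0.95) else NA_real_,
    mean = if (length(times)) mean(times) else NA_real_,
    throughput_mean = mean(per_rep$throughput),
    throughput_min = min(per_rep$throughput),
    throughput_max = max(per_rep$throughput),
    wastage_mean = mean(per_rep$wastage),
    max_staff_util = if (length(staff_mean)) max(staff_mean) else NA_real_
  )
  structure(
    list(pooled = pooled, per_rep = per_rep, util = util_pooled, times = times),
    class = "vax_summary"
  )
}

#' @export
print.vax_summary <- function(x, ...) {
  cat("<pooled simulation summary>\n")
  print(x$pooled)
  invisible(x)
}
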