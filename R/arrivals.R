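#' Build an appointment schedule
#'
#' Appointment-driven clinics run for eight hours (480 minutes, clock 0 =
#' opening). Mass vaccination hubs issue appointments on the hour (8 hourly
#' slots); GP clinics issue them every ten minutes (48 slots). The number of
#' appointments issued per slot at the published low/medium/high capacity
#' levels is 60/120/180 for hubs and 2/4/6 for GP clinics.
#'
#' @param site `"hub"` or `"gp"`.
#' @param level `"low"`, `"medium"` or `"high"`. Ignored when
#'   `bookings_per_slot` is supplied.
#' @param bookings_per_slot Optional explicit appointments per slot
#'   (single non-negative integer, recycled over slots, or one value per
#'   slot).
#' @return A tibble of class `vax_schedule` with columns `slot`,
#'   `slot_time` (minutes from opening) and `bookings`; attributes `site`
#'   and `slot_interval`.
#' @examples
#' build_schedule("hub", "medium") # 8 slots x 120 bookings
#' @export
build_schedule <- function(site = c("hub", "gp"),
                           level = c("low", "medium", "high"),
                           bookings_per_slot = NULL) {
  site <- tryCatch(match.arg(site),
    error = function(e) abort_config("`site` must be 'hub' or 'gp'.")
  )
  slot_interval <- if (site == "hub") 60 else 10
  n_slots <- 480 / slot_interval
  if (is.null(bookings_per_slot)) {
    level <- tryCatch(match.arg(level),
      error = function(e) {
        abort_config("`level` must be 'low', 'medium' or 'high'.")
      }
    )
    per_slot <- switch(site,
      hub = c(low = 60, medium = 120, high = 180)[[level]],
      gp = c(low = 2, medium = 4, high = 6)[[level]]
    )
    bookings <- rep(per_slot, n_slots)
  } else {
    if (!is.numeric(bookings_per_slot) || anyNA(bookings_per_slot) ||
      any(bookings_per_slot < 0) ||
      any(bookings_per_slot != round(bookings_per_slot))) {
      abort_config("`bookings_per_slot` must be non-negative integer(s).")
    }
    if (!length(bookings_per_slot) %in% c(1, n_slots)) {
      abort_config(paste0(
        "`bookings_per_slot` must have length 1 or ", n_slots,
        " for a ", site, " schedule."
      ))
    }
    bookings <- rep_len(as.numeric(bookings_per_slot), n_slots)
  }
  out <- tibble(
    slot = seq_len(n_slots),
    slot_time = (seq_len(n_slots) - 1) * slot_interval,
    bookings = bookings
  )
  structure(out,
    site = site, slot_interval = slot_interval,
    class = c("vax_schedule", class(out))
  )
}

#' Add extra appointments to every slot
#'
#' The arrival what-if sweep increases demand uniformly: ten additional
#' arrivals per hour for hubs, one additional arrival per ten-minute slot
#' for GP clinics, per increment step.
#'
#' @param schedule A [build_schedule()] result.
#' @param extra_per_slot Non-negative integer added to every slot.
#' @return The schedule with `bookings` increased uniformly.
#' @export
increment_schedule <- function(schedule, extra_per_slot) {
  if (!inherits(schedule, "vax_schedule")) {
    abort_config("`schedule` must be a `vax_schedule`.")
  }
  if (!is_count(extra_per_slot)) {
    abort_domain("`extra_per_slot` must be a non-negative integer.")
  }
  schedule$bookings <- schedule$bookings + extra_per_slot
  schedule
}

#' Arrival-noise and no-show specification
#'
#' Booked patients do not arrive exactly on their slot time: most arrive
#' somewhat early, a small proportion on or after. The default offset is
#' Normal(-10, 5) minutes (median ten minutes early, with about 2.3% of
#' patients arriving at or after their allotted time); arrivals falling
#' before opening are clamped to the opening time. A small proportion of
#' bookings (default 2%) never show up.
#'
#' @param noise [dist_spec()] for the (arrival - appointment) offset in
#'   minutes; raw draws, negative values allowed.
#' @param no_show_prob Probability a booking is a no-show, default 0.02.
#' @return An object of class `vax_arrival_spec`.
#' @export
arrival_spec <- function(noise = dist_spec("normal", mean = -10, sd = 5),
                         no_show_prob = 0.02) {
  if (!inherits(noise, "vax_dist")) {
    abort_config("`noise` must be a `dist_spec()` object.")
  }
  if (!is_prob(no_show_prob)) {
    abort_config("`no_show_prob` must be a probability in [0, 1].")
  }
  structure(
    list(noise = noise, no_show_prob = no_show_prob),
    class = "vax_arrival_spec"
  )
}

#' Generate stochastic patient arrivals from a schedule
#'
#' One record per booking. Attendance flags are independent
#' Bernoulli(1 - `no_show_prob`); attended arrival times are
#' `max(0, slot_time + noise)`. Attended patients are ordered by arrival
#' time (no-shows follow, with `NA` arrival).
#'
#' @param schedule A [build_schedule()] result.
#' @param spec An [arrival_spec()].
#' @return A tibble of class `vax_arrivals` with columns `patient_id`,
#'   `slot_time`, `arrival_time` and `attended`.
#' @export
generate_arrivals <- function(schedule, spec = arrival_spec()) {
  if (!inherits(schedule, "vax_schedule")) {
    abort_config("`schedule` must be a `vax_schedule`.")
  }
  if (!inherits(spec, "vax_arrival_spec")) {
    abort_config("`spec` must be an `arrival_spec()`.")
  }
  slot <- rep(schedule$slot_time, times = schedule$bookings)
  n <- length(slot)
  attended <- runif(n) >= spec$no_show_prob
  noise <- sample_dist(spec$noise, n)
  arrival <- pmax(0, slot + noise)
  arrival[!attended] <- NA_real_
  out <- tibble(
    patient_id = seq_len(n),
    slot_time = slot,
    arrival_time = arrival,
    attended = attended
  )
  out <- dplyr::arrange(out, !.data$attended, .data$arrival_time, .data$patient_id)
  structure(out,
    site = attr(schedule, "site"),
    class = c("vax_arrivals", setdiff(class(out), "vax_arrivals"))
  )
}

#' Dose-demand release times for the preparation queue
#'
#' One vaccine dose is demanded per booking, released into the preparation
#' queue at the start of the booking's slot. Doses are prepared for all
#' bookings — preparation staff cannot foresee no-shows — so unconsumed
#' doses show up as wastage in the run summaries but have no queue effect.
#'
#' @param schedule A [build_schedule()] result.
#' @return Sorted numeric vector of release times (minutes from opening),
#'   one per booking.
#' @export
generate_dose_demand <- function(schedule) {
  if (!inherits(schedule, "vax_schedule")) {
    abort_config("`schedule` must be a `vax_schedule`.")
  }
  sort(rep(schedule$slot_time, times = schedule$bookings))
}
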