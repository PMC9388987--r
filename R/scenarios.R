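#' Scenario configuration
#'
#' Bundles everything one simulated scenario needs: the site and capacity
#' level (or explicit schedule / staffing overrides), the stochastic
#' parameters, the replication count and the base seed. All randomness in a
#' run flows from the base seed via [derive_seeds()], so every output is
#' reproducible and any single replication can be re-run on its own.
#'
#' @param site `"hub"` or `"gp"`.
#' @param level `"low"`, `"medium"` or `"high"`.
#' @param bookings_per_slot Optional explicit appointments per slot
#'   (overrides the level's published schedule).
#' @param staffing Optional named per-station staffing override (see
#'   [make_hub_network()] / [make_gp_network()]).
#' @param seats Optional observation-seat override.
#' @param reps Replications (independent simulated clinic days), default 20.
#' @param seed Base seed, default 1.
#' @param no_show_prob No-show probability, default 0.02.
#' @param adverse_prob Adverse-reaction probability, default 0.02.
#' @param noise [dist_spec()] for the arrival-time offset; default
#'   Normal(-10, 5) minutes.
#' @param walk_lag [dist_spec()] for hub walking lags, default
#'   Uniform(0.5, 2) minutes; ignored for GP sites (no lags).
#' @return A list of class `vax_scenario`.
#' @export
scenario_config <- function(site = c("hub", "gp"),
                            level = c("low", "medium", "high"),
                            bookings_per_slot = NULL,
                            staffing = NULL,
                            seats = NULL,
                            reps = 20,
                            seed = 1L,
                            no_show_prob = 0.02,
                            adverse_prob = 0.02,
                            noise = dist_spec("normal", mean = -10, sd = 5),
                            walk_lag = dist_spec("uniform", min = 0.5, max = 2)) {
  site <- tryCatch(match.arg(site),
    error = function(e) abort_config("`site` must be 'hub' or 'gp'.")
  )
  level <- tryCatch(match.arg(level),
    error = function(e) {
      abort_config("`level` must be 'low', 'medium' or 'high'.")
    }
  )
  if (!is_count(reps, min = 1)) {
    abort_config("`reps` must be an integer >= 1.")
  }
  if (!is_prob(no_show_prob)) {
    abort_config("`no_show_prob` must be a probability in [0, 1].")
  }
  if (!is_prob(adverse_prob)) {
    abort_config("`adverse_prob` must be a probability in [0, 1].")
  }
  structure(
    list(
      site = site, level = level,
      bookings_per_slot = bookings_per_slot,
      staffing = staffing, seats = seats,
      reps = as.integer(reps), seed = as.integer(seed),
      no_show_prob = no_show_prob, adverse_prob = adverse_prob,
      noise = noise, walk_lag = walk_lag
    ),
    class = "vax_scenario"
  )
}

scenario_network <- function(config) {
  if (config$site == "hub") {
    make_hub_network(config$level,
      staffing = config$staffing, seats = config$seats,
      walk_lag = config$walk_lag, adverse_prob = config$adverse_prob
    )
  } else {
    make_gp_network(config$level,
      staffing = config$staffing, seats = config$seats,
      adverse_prob = config$adverse_prob
    )
  }
}

scenario_schedule <- function(config) {
  build_schedule(config$site, config$level,
    bookings_per_slot = config$bookings_per_slot
  )
}

#' Simulate a single clinic day
#'
#' Generates arrivals and dose demand from the schedule, then runs the
#' network. All draws come from the supplied seed.
#'
#' @param network A `vax_network`.
#' @param schedule A `vax_schedule`.
#' @param spec An [arrival_spec()].
#' @param seed Integer seed for this replication.
#' @return A `vax_log` (see [simulate_network()]).
#' @export
simulate_day <- function(network, schedule, spec = arrival_spec(), seed = 1L) {
  set.seed(as.integer(seed))
  arrivals <- generate_arrivals(schedule, spec)
  doses <- generate_dose_demand(schedule)
  simulate_network(network, arrivals, doses)
}

#' Run a baseline scenario
#'
#' Simulates `config$reps` independent clinic days (per-replication seeds
#' derived deterministically from the base seed) and pools the results.
#'
#' @param config A [scenario_config()].
#' @param keep_logs Keep per-replication patient logs on the result
#'   (needed by [write_outputs()]); default `TRUE`.
#' @return A list of class `vax_run`: `config`, `seeds`, `summary`
#'   (a [summarize_reps()] result) and optionally `logs`.
#' @export
run_baseline <- function(config, keep_logs = TRUE) {
  if (!inherits(config, "vax_scenario")) {
    abort_config("`config` must be a `scenario_config()`.")
  }
  network <- scenario_network(config)
  schedule <- scenario_schedule(config)
  spec <- arrival_spec(noise = config$noise, no_show_prob = config$no_show_prob)
  seeds <- derive_seeds(config$seed, config$reps)
  logs <- vector("list", config$reps)
  summaries <- vector("list", config$reps)
  for (r in seq_len(config$reps)) {
    log <- simulate_day(network, schedule, spec, seed = seeds[r])
    summaries[[r]] <- summarize_log(log, rep = r, seed = seeds[r])
    if (keep_logs) logs[[r]] <- log
  }
  structure(
    list(
      config = config,
      network = network,
      schedule = schedule,
      seeds = seeds,
      summary = summarize_reps(summaries),
      logs = if (keep_logs) logs else NULL
    ),
    class = "vax_run"
  )
}

#' @export
print.vax_run <- function(x, ...) {
  cat(
    "<scenario run> site =", x$config$site, " level =", x$config$level,
    " reps =", x$config$reps, " seed =", x$config$seed, "\n"
  )
  print(x$summary$pooled)
  invisible(x)
}

#' @export
tidy.vax_run <- function(x, ...) {
  x$summary$per_rep
}

#' @export
glance.vax_run <- function(x, ...) {
  dplyr::mutate(x$summary$pooled,
    site = x$config$site, level = x$config$level,
    seed = x$config$seed, .before = 1
  )
}

# Site-specific default increment: +10/hour for hubs, +1/slot for GPs.
default_step <- function(site) if (site == "hub") 10 else 1

#' What-if sweep: increasing arrivals
#'
#' Re-runs the scenario with the appointment schedule incremented uniformly
#' by the site-specific step (ten additional arrivals per hour for hubs,
#' one additional arrival per ten-minute slot for GP clinics) per sweep
#' point, including the unmodified baseline as step 0. Sweep points use
#' independent seeds derived from the base seed (independent-scenario
#' design); set `common_random_numbers = TRUE` to reuse the base seed at
#' every point for variance-reduced comparisons.
#'
#' @param config A [scenario_config()].
#' @param n_steps Number of increments beyond baseline (`>= 1`).
#' @param step Bookings added per slot per step; default [default_step()]
#'   by site.
#' @param common_random_numbers Reuse the same seed across sweep points.
#' @param keep_runs Keep the full `vax_run` objects in a list-column.
#' @return A tibble of class `vax_sweep`, one row per sweep point.
#' @export
whatif_arrivals <- function(config, n_steps = 5, step = NULL,
                            common_random_numbers = FALSE,
                            keep_runs = FALSE) {
  if (!inherits(config, "vax_scenario")) {
    abort_config("`config` must be a `scenario_config()`.")
  }
  if (!is_count(n_steps, min = 1)) {
    abort_domain("`n_steps` must be an integer >= 1.")
  }
  step <- step %||% default_step(config$site)
  if (!is_count(step)) abort_domain("`step` must be a non-negative integer.")
  base_schedule <- scenario_schedule(config)
  extras <- (0:n_steps) * step
  point_seeds <- if (common_random_numbers) {
    rep(config$seed, length(extras))
  } else {
    derive_seeds(config$seed, length(extras))
  }
  rows <- purrr::imap(extras, function(extra, i) {
    cfg <- config
    cfg$bookings_per_slot <- increment_schedule(base_schedule, extra)$bookings
    cfg$seed <- point_seeds[i]
    run <- run_baseline(cfg, keep_logs = FALSE)
    p <- run$summary$pooled
    tibble(
      step = i - 1L,
      extra_per_slot = extra,
      bookings_per_slot = cfg$bookings_per_slot[1],
      total_bookings = sum(cfg$bookings_per_slot),
      feasible = TRUE,
      median = p$median,
      p95 = p$p95,
      throughput_mean = p$throughput_mean,
      max_staff_util = p$max_staff_util,
      run = if (keep_runs) list(run) else list(NULL)
    )
  })
  out <- purrr::list_rbind(rows)
  if (!keep_runs) out$run <- NULL
  structure(out,
    sweep = "arrivals", site = config$site, level = config$level,
    class = c("vax_sweep", setdiff(class(out), "vax_sweep"))
  )
}

#' What-if sweep: decreasing staff
#'
#' Re-runs the scenario with 0, 1, ..., `max_reduction` staff removed via
#' [reduce_staff()]. Reductions that would leave a staffed station empty
#' are flagged infeasible (metrics `NA`), not silently dropped.
#'
#' @param config A [scenario_config()].
#' @param max_reduction Largest number of staff removed (`>= 1`).
#' @inheritParams whatif_arrivals
#' @return A tibble of class `vax_sweep`, one row per reduction.
#' @export
whatif_staff <- function(config, max_reduction = 3,
                         common_random_numbers = FALSE,
                         keep_runs = FALSE) {
  if (!inherits(config, "vax_scenario")) {
    abort_config("`config` must be a `scenario_config()`.")
  }
  if (!is_count(max_reduction, min = 1)) {
    abort_domain("`max_reduction` must be an integer >= 1.")
  }
  base_network <- scenario_network(config)
  ks <- 0:max_reduction
  point_seeds <- if (common_random_numbers) {
    rep(config$seed, length(ks))
  } else {
    derive_seeds(config$seed, length(ks))
  }
  rows <- purrr::imap(ks, function(k, i) {
    reduced <- tryCatch(reduce_staff(base_network, k),
      vaxflow_infeasible_error = function(e) NULL,
      vaxflow_domain_error = function(e) NULL
    )
    if (is.null(reduced)) {
      return(tibble(
        step = i - 1L, staff_removed = k,
        total_staff = NA_integer_, feasible = FALSE,
        median = NA_real_, p95 = NA_real_,
        throughput_mean = NA_real_, max_staff_util = NA_real_,
        run = list(NULL)
      ))
    }
    cfg <- config
    cfg$staffing <- staff_counts(reduced)
    cfg$seed <- point_seeds[i]
    run <- run_baseline(cfg, keep_logs = FALSE)
    p <- run$summary$pooled
    tibble(
      step = i - 1L, staff_removed = k,
      total_staff = total_staff(reduced), feasible = TRUE,
      median = p$median, p95 = p$p95,
      throughput_mean = p$throughput_mean,
      max_staff_util = p$max_staff_util,
      run = if (keep_runs) list(run) else list(NULL)
    )
  })
  out <- purrr::list_rbind(rows)
  if (!keep_runs) out$run <- NULL
  structure(out,
    sweep = "staff", site = config$site, level = config$level,
    class = c("vax_sweep", setdiff(class(out), "vax_sweep"))
  )
}

#' @export
tidy.vax_sweep <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.vax_sweep <- function(x, ...) {
  tibble(
    sweep = attr(x, "sweep"),
    site = attr(x, "site"),
    level = attr(x, "level"),
    points = nrow(x),
    feasible_points = sum(x$feasible),
    max_median = max(x$median, na.rm = TRUE)
  )
}

#' Calibrate the appointment schedule to service constraints
#'
#' Finds the largest integer bookings-per-slot such that, over `reps`
#' replications, the pooled median processing time stays strictly below
#' `median_max` and every staffed station's utilisation stays strictly
#' below `util_max` (mirroring the published "remained below" constraints:
#' 60 minutes and 0.8). The search doubles the booking level until it turns
#' infeasible, then bisects on the integer grid. Each candidate level is
#' evaluated with its own seed derived from the base seed.
#'
#' @param site `"hub"` or `"gp"`.
#' @param level `"low"`, `"medium"` or `"high"`.
#' @param median_max Processing-time bound in minutes, default 60.
#' @param util_max Staff-utilisation bound, default 0.8.
#' @param reps Replications per candidate, default 20.
#' @param seed Base seed.
#' @param ... Passed to [scenario_config()] (e.g. `staffing`, `noise`).
#' @return A list of class `vax_calibration`: `bookings_per_slot` (the
#'   largest feasible level), `trace` (every candidate evaluated, with its
#'   metrics) and the constraints.
#' @export
calibrate_appointments <- function(site, level,
                                   median_max = 60, util_max = 0.8,
                                   reps = 20, seed = 1L, ...) {
  if (!is.numeric(median_max) || length(median_max) != 1 ||
    !is.numeric(util_max) || length(util_max) != 1) {
    abort_config("`median_max` and `util_max` must be single numbers.")
  }
  trace <- list()
  evaluate <- function(b) {
    cfg <- scenario_config(
      site = site, level = level, bookings_per_slot = b,
      reps = reps, seed = derive_seeds((seed + b) %% 2147483647L, 1), ...
    )
    run <- run_baseline(cfg, keep_logs = FALSE)
    p <- run$summary$pooled
    feasible <- is.finite(p$median) &&
      p$median < median_max && p$max_staff_util < util_max
    trace[[length(trace) + 1]] <<- tibble(
      bookings_per_slot = b, median = p$median,
      max_staff_util = p$max_staff_util, feasible = feasible
    )
    feasible
  }
  if (median_max <= 0 || util_max <= 0 || !evaluate(1L)) {
    abort_infeasible(paste0(
      "No positive booking level satisfies median < ", median_max,
      " min and utilisation < ", util_max, " for the ", level, " ", site, "."
    ))
  }
  lo <- 1L # largest known-feasible
  hi <- NA_integer_ # smallest known-infeasible
  b <- 2L
  while (is.na(hi) && b <= 16384L) {
    if (evaluate(b)) lo <- b else hi <- b
    if (is.na(hi)) b <- b * 2L
  }
  if (is.na(hi)) {
    abort_domain("Calibration did not find an infeasible level below 16384.")
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (evaluate(mid)) lo <- mid else hi <- mid
  }
  structure(
    list(
      site = site, level = level,
      bookings_per_slot = lo,
      median_max = median_max, util_max = util_max,
      reps = reps, seed = seed,
      trace = dplyr::arrange(purrr::list_rbind(trace), .data$bookings_per_slot)
    ),
    class = "vax_calibration"
  )
}

#' @export
print.vax_calibration <- function(x, ...) {
  cat(
    "<appointment calibration> ", x$site, "/", x$level,
    ": max feasible bookings per slot = ", x$bookings_per_slot,
    " (median < ", x$median_max, " min, utilisation < ", x$util_max, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.vax_calibration <- function(x, ...) {
  x$trace
}

#' @export
glance.vax_calibration <- function(x, ...) {
  tibble(
    site = x$site, level = x$level,
    bookings_per_slot = x$bookings_per_slot,
    median_max = x$median_max, util_max = x$util_max, reps = x$reps
  )
}
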