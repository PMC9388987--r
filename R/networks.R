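#' Station configuration
#'
#' @param name Station label (lower-case, used for log column names).
#' @param n_servers Number of parallel servers (staff, or seats for the
#'   observation area).
#' @param service A [dist_spec()] or [obs_mixture()].
#' @param role `"staff"` for staffed stations, `"seats"` for the
#'   observation area (seats are capacity, not staff).
#' @return A list of class `vax_station`.
#' @export
vax_station <- function(name, n_servers, service, role = c("staff", "seats")) {
  role <- match.arg(role)
  if (!is_count(n_servers, min = 1)) {
    abort_config(paste0("Station '", name, "' must have at least one server."))
  }
  if (!inherits(service, "vax_dist") && !inherits(service, "vax_mixture")) {
    abort_config(paste0(
      "Station '", name, "' needs a `dist_spec()` or `obs_mixture()` service."
    ))
  }
  structure(
    list(
      name = name, n_servers = as.integer(n_servers),
      service = service, role = role
    ),
    class = "vax_station"
  )
}

# Published staffing tables: servers per station at each capacity level.
hub_staffing <- function(level) {
  switch(level,
    low = c(preparation = 2, entrance = 4, registration = 6, assessment = 4, vaccination = 5),
    medium = c(preparation = 4, entrance = 8, registration = 12, assessment = 8, vaccination = 10),
    high = c(preparation = 6, entrance = 12, registration = 18, assessment = 12, vaccination = 15)
  )
}

gp_staffing <- function(level) {
  switch(level,
    low = c(preparation = 1, registration = 1, vaccination = 2),
    medium = c(preparation = 2, registration = 2, vaccination = 4),
    high = c(preparation = 3, registration = 3, vaccination = 6)
  )
}

hub_seats <- c(low = 25, medium = 50, high = 75)
gp_seats <- c(low = 5, medium = 10, high = 15)

check_level <- function(level) {
  if (!is.character(level) || length(level) != 1 ||
    !level %in% c("low", "medium", "high")) {
    abort_config("`level` must be 'low', 'medium' or 'high'.")
  }
  level
}

# Merge a (possibly partial) named staffing override into level defaults.
check_staffing <- function(staffing, expected) {
  if (is.null(staffing)) {
    return(expected)
  }
  staffing <- unlist(staffing)
  unknown <- setdiff(names(staffing), names(expected))
  if (is.null(names(staffing)) || length(unknown) > 0) {
    abort_config(paste0(
      "`staffing` must be named with entries among: ",
      paste(names(expected), collapse = ", "),
      if (length(unknown) > 0) {
        paste0(" (unknown: ", paste(unknown, collapse = ", "), ")")
      }, "."
    ))
  }
  out <- expected
  out[names(staffing)] <- staffing
  if (any(out < 1) || any(out != round(out))) {
    abort_config("Every staffed station needs an integer count >= 1.")
  }
  out
}

#' Assemble a custom queue network
#'
#' Builds a network from explicit station configurations, for layouts other
#' than the two published presets. Patients traverse `stations` in order;
#' the dose-preparation queue (`prep`) runs in parallel and joins the
#' patient queue at the station named `"vaccination"`, if present.
#'
#' @param site Site label (free text; `"hub"`/`"gp"` for the presets).
#' @param stations List of [vax_station()] in patient order.
#' @param prep A [vax_station()] for dose preparation.
#' @param walk_lag Optional [dist_spec()] applied between consecutive
#'   stations; `NULL` for none.
#' @param level Optional capacity label.
#' @return A list of class `vax_network`.
#' @export
vax_network <- function(site, stations, prep, walk_lag = NULL, level = NULL) {
  if (!is.list(stations) || length(stations) == 0 ||
    !all(vapply(stations, inherits, logical(1), "vax_station"))) {
    abort_config("`stations` must be a non-empty list of `vax_station()`s.")
  }
  if (!inherits(prep, "vax_station")) {
    abort_config("`prep` must be a `vax_station()`.")
  }
  if (!is.null(walk_lag) && !inherits(walk_lag, "vax_dist")) {
    abort_config("`walk_lag` must be a `dist_spec()` or NULL.")
  }
  structure(
    list(
      site = site, level = level, prep = prep,
      stations = stations, walk_lag = walk_lag
    ),
    class = "vax_network"
  )
}

#' Mass-vaccination-hub queue network
#'
#' Patients traverse five stations in order — Entrance, Registration,
#' Assessment, Vaccination and Observation — with a short walking lag
#' between consecutive stations and a parallel dose-preparation queue that
#' joins the patient queue at Vaccination. Service-time distributions:
#' preparation 1 + exp(3), entrance 2 + exp(1), registration 3 + exp(0.7),
#' assessment 2 + exp(1), vaccination 3 + exp(1), observation a
#' Normal(20, 0.5) / 20 + exp(0.1) adverse mixture. Published staffing
#' (preparation, entrance, registration, assessment, vaccination) is
#' (2,4,6,4,5), (4,8,12,8,10) and (6,12,18,12,15) with 25/50/75 observation
#' seats at the low/medium/high levels (21/42/63 total staff).
#'
#' @param level `"low"`, `"medium"` or `"high"`.
#' @param staffing Optional named vector overriding servers per staffed
#'   station (names `preparation`, `entrance`, `registration`,
#'   `assessment`, `vaccination`).
#' @param seats Optional observation-seat count override.
#' @param walk_lag [dist_spec()] for the walking time applied after each of
#'   the first four stations; default Uniform(0.5, 2) minutes. `NULL`
#'   disables lags.
#' @param adverse_prob Adverse-reaction probability, default 0.02.
#' @return A list of class `vax_network`.
#' @export
make_hub_network <- function(level = c("low", "medium", "high"),
                             staffing = NULL, seats = NULL,
                             walk_lag = dist_spec("uniform", min = 0.5, max = 2),
                             adverse_prob = 0.02) {
  if (identical(level, c("low", "medium", "high"))) level <- "low"
  level <- check_level(level)
  counts <- check_staffing(staffing, hub_staffing(level))
  seats <- seats %||% hub_seats[[level]]
  if (!is_count(seats, min = 1)) {
    abort_config("`seats` must be an integer >= 1.")
  }
  obs <- obs_mixture(adverse_prob = adverse_prob)
  structure(
    list(
      site = "hub",
      level = level,
      prep = vax_station(
        "preparation", counts[["preparation"]],
        dist_spec("exponential", shift = 1, rate = 3)
      ),
      stations = list(
        vax_station(
          "entrance", counts[["entrance"]],
          dist_spec("exponential", shift = 2, rate = 1)
        ),
        vax_station(
          "registration", counts[["registration"]],
          dist_spec("exponential", shift = 3, rate = 0.7)
        ),
        vax_station(
          "assessment", counts[["assessment"]],
          dist_spec("exponential", shift = 2, rate = 1)
        ),
        vax_station(
          "vaccination", counts[["vaccination"]],
          dist_spec("exponential", shift = 3, rate = 1)
        ),
        vax_station("observation", seats, obs, role = "seats")
      ),
      walk_lag = walk_lag
    ),
    class = "vax_network"
  )
}

#' General-practice-clinic queue network
#'
#' Patients traverse three stations — Registration, Vaccination and
#' Observation — with negligible walking time (no lags). A parallel
#' dose-preparation queue joins at Vaccination. Service-time distributions:
#' preparation 1 + exp(3), registration 3 + exp(1), vaccination
#' 5 + exp(0.5), observation the Normal(20, 0.5) / 20 + exp(0.1) adverse
#' mixture. Published staffing (preparation, registration, vaccination) is
#' (1,1,2), (2,2,4) and (3,3,6) with 5/10/15 observation seats at the
#' low/medium/high levels (4/8/12 total staff).
#'
#' @inheritParams make_hub_network
#' @param staffing Optional named override (names `preparation`,
#'   `registration`, `vaccination`).
#' @return A list of class `vax_network`.
#' @export
make_gp_network <- function(level = c("low", "medium", "high"),
                            staffing = NULL, seats = NULL,
                            adverse_prob = 0.02) {
  if (identical(level, c("low", "medium", "high"))) level <- "low"
  level <- check_level(level)
  counts <- check_staffing(staffing, gp_staffing(level))
  seats <- seats %||% gp_seats[[level]]
  if (!is_count(seats, min = 1)) {
    abort_config("`seats` must be an integer >= 1.")
  }
  obs <- obs_mixture(adverse_prob = adverse_prob)
  structure(
    list(
      site = "gp",
      level = level,
      prep = vax_station(
        "preparation", counts[["preparation"]],
        dist_spec("exponential", shift = 1, rate = 3)
      ),
      stations = list(
        vax_station(
          "registration", counts[["registration"]],
          dist_spec("exponential", shift = 3, rate = 1)
        ),
        vax_station(
          "vaccination", counts[["vaccination"]],
          dist_spec("exponential", shift = 5, rate = 0.5)
        ),
        vax_station("observation", seats, obs, role = "seats")
      ),
      walk_lag = NULL
    ),
    class = "vax_network"
  )
}

make_network <- function(site, level, ...) {
  switch(site,
    hub = make_hub_network(level, ...),
    gp = make_gp_network(level, ...),
    abort_config("`site` must be 'hub' or 'gp'.")
  )
}

staff_counts <- function(network) {
  staffed <- Filter(function(s) s$role == "staff", network$stations)
  counts <- c(
    network$prep$n_servers,
    vapply(staffed, function(s) s$n_servers, numeric(1))
  )
  names(counts) <- c(
    network$prep$name,
    vapply(staffed, function(s) s$name, character(1))
  )
  counts
}

#' Total staff in a network
#'
#' Counts servers at staffed stations, including dose preparation;
#' observation seats (and any supervising staff) are excluded.
#'
#' @param network A `vax_network`.
#' @return Integer total.
#' @export
total_staff <- function(network) {
  sum(staff_counts(network))
}

#' Remove staff for a shortage scenario
#'
#' Removes `k` staff one at a time. Within each removal cycle, stations are
#' ranked by current server count (largest first, ties broken toward the
#' more downstream station) and lose one server each in that order, skipping
#' stations already at one server. This keeps the network's proportional
#' staffing shape as close to the published layout as possible. No staffed
#' station may drop below one server.
#'
#' @param network A `vax_network`.
#' @param k Number of staff to remove (`0 <= k <` total staff).
#' @return The reduced network.
#' @examples
#' reduce_staff(make_hub_network("low"), 3) # (2,4,6,4,5) -> (2,4,5,3,4)
#' @export
reduce_staff <- function(network, k) {
  if (!inherits(network, "vax_network")) {
    abort_config("`network` must be a `vax_network`.")
  }
  if (!is_count(k)) abort_domain("`k` must be a non-negative integer.")
  total <- total_staff(network)
  if (k >= total) {
    abort_domain(paste0(
      "Cannot remove ", k, " staff from a network with ", total, " staff."
    ))
  }
  counts <- staff_counts(network)
  remaining <- k
  while (remaining > 0) {
    ord <- order(-counts, -seq_along(counts))
    removed <- FALSE
    for (j in ord) {
      if (remaining == 0) break
      if (counts[j] > 1) {
        counts[j] <- counts[j] - 1
        remaining <- remaining - 1
        removed <- TRUE
      }
    }
    if (!removed && remaining > 0) {
      abort_infeasible(paste0(
        "Removing ", k, " staff would leave a station without any server ",
        "(every staffed station must keep at least 1)."
      ))
    }
  }
  network$prep$n_servers <- as.integer(counts[[network$prep$name]])
  network$stations <- lapply(network$stations, function(s) {
    if (s$role == "staff") s$n_servers <- as.integer(counts[[s$name]])
    s
  })
  network
}

#' @export
tidy.vax_network <- function(x, ...) {
  tibble(
    station = c(
      x$prep$name,
      vapply(x$stations, function(s) s$name, character(1))
    ),
    n_servers = c(
      x$prep$n_servers,
      vapply(x$stations, function(s) s$n_servers, numeric(1))
    ),
    role = c(
      x$prep$role,
      vapply(x$stations, function(s) s$role, character(1))
    ),
    service = c(
      format(x$prep$service),
      vapply(x$stations, function(s) format(s$service), character(1))
    )
  )
}

#' @export
print.vax_network <- function(x, ...) {
  cat(
    "<vaccination queue network> site =", x$site, " level =",
    x$level %||% "(custom)", "\n"
  )
  cat(
    " total staff:", total_staff(x), " walk lag:",
    if (is.null(x$walk_lag)) "none" else format(x$walk_lag), "\n"
  )
  print(tidy(x))
  invisible(x)
}
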