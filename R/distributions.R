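#' Shifted parametric service-time distributions
#'
#' A `dist_spec` describes a service (or lag, or arrival-noise) duration as a
#' fixed minimum `shift` plus a draw from a base parametric family:
#' `value = shift + base`. Five service families are supported —
#' exponential (`rate`), normal (`mean`, `sd`), lognormal (`meanlog`,
#' `sdlog`), gamma (`shape`, `rate`) and weibull (`shape`, `scale`) — plus
#' `uniform` (`min`, `max`) for walking lags and `deterministic` (`value`)
#' for degenerate/noiseless cases. The base draw is non-negative by
#' construction for the exponential, lognormal, gamma and weibull families;
#' for families that admit negative draws (normal, uniform), service-time
#' sampling rejects and redraws values below the shift, so sampled service
#' times always satisfy `value >= shift`.
#'
#' The exponential family is parameterised by its *rate* \eqn{\lambda}: a
#' station written `3 + exp(rate = 0.7)` has median
#' \eqn{3 + \ln 2 / 0.7 \approx 4.0} minutes.
#'
#' @param family One of `"exponential"`, `"normal"`, `"lognormal"`,
#'   `"gamma"`, `"weibull"`, `"uniform"`, `"deterministic"`.
#' @param shift Fixed minimum duration in minutes (non-negative).
#' @param ... Family parameters, named (see above).
#' @return An object of class `vax_dist`.
#' @examples
#' reg <- dist_spec("exponential", shift = 3, rate = 0.7)
#' quantile(reg, 0.5) # ~ 3.99 minutes
#' @export
dist_spec <- function(family, shift = 0, ...) {
  if (!is.character(family) || length(family) != 1) {
    abort_config("`family` must be a single string.")
  }
  families <- c(
    "exponential", "normal", "lognormal", "gamma", "weibull",
    "uniform", "deterministic"
  )
  if (!family %in% families) {
    abort_config(paste0(
      "Unknown distribution family '", family, "'. Supported families: ",
      paste(families, collapse = ", "), "."
    ))
  }
  if (!is.numeric(shift) || length(shift) != 1 || is.na(shift) || shift < 0) {
    abort_config("`shift` must be a single non-negative number of minutes.")
  }
  params <- list(...)
  req <- switch(family,
    exponential = "rate",
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    gamma = c("shape", "rate"),
    weibull = c("shape", "scale"),
    uniform = c("min", "max"),
    deterministic = "value"
  )
  missing <- setdiff(req, names(params))
  if (length(missing) > 0) {
    abort_config(paste0(
      "Missing parameter(s) for family '", family, "': ",
      paste(missing, collapse = ", "), "."
    ))
  }
  extra <- setdiff(names(params), req)
  if (length(extra) > 0) {
    abort_config(paste0(
      "Unknown parameter(s) for family '", family, "': ",
      paste(extra, collapse = ", "), "."
    ))
  }
  for (nm in req) {
    p <- params[[nm]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p)) {
      abort_config(paste0("Parameter `", nm, "` must be a single number."))
    }
  }
  check_pos <- function(nm) {
    if (params[[nm]] <= 0) {
      abort_config(paste0(
        "Parameter `", nm, "` must be positive for the ", family, " family."
      ))
    }
  }
  switch(family,
    exponential = check_pos("rate"),
    normal = check_pos("sd"),
    lognormal = check_pos("sdlog"),
    gamma = {
      check_pos("shape")
      check_pos("rate")
    },
    weibull = {
      check_pos("shape")
      check_pos("scale")
    },
    uniform = {
      if (params$min > params$max) {
        abort_config("`min` must not exceed `max` for the uniform family.")
      }
    },
    deterministic = NULL
  )
  structure(
    list(family = family, shift = shift, params = params[req]),
    class = "vax_dist"
  )
}

#' @export
format.vax_dist <- function(x, ...) {
  pars <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  core <- paste0(x$family, "(", pars, ")")
  if (x$shift > 0) paste0(x$shift, " + ", core) else core
}

#' @export
print.vax_dist <- function(x, ...) {
  cat("<service-time distribution> ", format(x), "\n", sep = "")
  invisible(x)
}

# Raw draw: shift + base, no truncation (used for arrival-noise offsets,
# which may legitimately be negative).
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "vax_dist"))
  if (!is_count(n)) abort_domain("`n` must be a non-negative integer count.")
  p <- spec$params
  base <- switch(spec$family,
    exponential = rexp(n, rate = p$rate),
    normal = rnorm(n, mean = p$mean, sd = p$sd),
    lognormal = rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    gamma = rgamma(n, shape = p$shape, rate = p$rate),
    weibull = rweibull(n, shape = p$shape, scale = p$scale),
    uniform = runif(n, min = p$min, max = p$max),
    deterministic = rep(p$value, n)
  )
  spec$shift + base
}

# Probability that a single raw draw falls below the shift (base < 0).
prob_below_shift <- function(spec) {
  p <- spec$params
  switch(spec$family,
    normal = pnorm(0, mean = p$mean, sd = p$sd),
    uniform = punif(0, min = p$min, max = p$max),
    deterministic = as.numeric(p$value < 0),
    0
  )
}

#' Sample service times from a shifted distribution
#'
#' Draws `n` independent service durations. Values are guaranteed to be at
#' least `spec$shift`: for families whose base draw can be negative (normal,
#' uniform), negative base draws are rejected and resampled. With the
#' clinic parameters used here (e.g. observation times Normal(20, 0.5)) the
#' rejection branch is never triggered in practice.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws (non-negative integer).
#' @return Numeric vector of length `n`, durations in minutes, all
#'   `>= spec$shift`. Reproducible under [set.seed()].
#' @export
sample_service_times <- function(spec, n) {
  if (inherits(spec, "vax_mixture")) {
    return(sample_observation(spec, n)$duration)
  }
  if (!inherits(spec, "vax_dist")) {
    abort_config("`spec` must be a `dist_spec()` object.")
  }
  if (prob_below_shift(spec) >= 1) {
    abort_config(paste0(
      "Distribution ", format(spec),
      " cannot produce non-negative service times."
    ))
  }
  x <- sample_dist(spec, n)
  bad <- which(x < spec$shift)
  guard <- 0L
  while (length(bad) > 0) {
    x[bad] <- sample_dist(spec, length(bad))
    bad <- bad[x[bad] < spec$shift]
    guard <- guard + 1L
    if (guard > 10000L) {
      abort_config(paste0(
        "Rejection sampling failed to produce draws >= shift for ",
        format(spec), "."
      ))
    }
  }
  x
}

#' Quantiles of a shifted service-time distribution
#'
#' Closed-form quantile `shift + F^{-1}(p)` of the base family. For families
#' whose base draw can be negative (normal, uniform) the quantile is that of
#' the base distribution truncated at zero, matching the rejection rule used
#' by [sample_service_times()].
#'
#' @param x A [dist_spec()].
#' @param probs Probabilities, all strictly inside (0, 1).
#' @param ... Unused.
#' @return Numeric vector of quantiles (minutes), non-decreasing in `probs`.
#' @export
quantile.vax_dist <- function(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95), ...) {
  if (!is.numeric(probs) || length(probs) == 0 || anyNA(probs) ||
    any(probs <= 0) || any(probs >= 1)) {
    abort_domain("`probs` must lie strictly within (0, 1).")
  }
  p <- x$params
  # truncation of the base distribution at 0
  f0 <- prob_below_shift(x)
  pr <- probs * (1 - f0) + f0
  base <- switch(x$family,
    exponential = qexp(pr, rate = p$rate),
    normal = qnorm(pr, mean = p$mean, sd = p$sd),
    lognormal = qlnorm(pr, meanlog = p$meanlog, sdlog = p$sdlog),
    gamma = qgamma(pr, shape = p$shape, rate = p$rate),
    weibull = qweibull(pr, shape = p$shape, scale = p$scale),
    uniform = qunif(pr, min = p$min, max = p$max),
    deterministic = rep(max(p$value, 0), length(pr))
  )
  x$shift + base
}

#' Bimodal observation-time mixture
#'
#' Post-vaccination observation times are bimodal: most patients sit for a
#' roughly fixed observation period (normal component), while a small random
#' subset experience an adverse reaction and stay much longer (shifted
#' exponential component). Each patient carries an adverse flag drawn as an
#' independent Bernoulli(`adverse_prob`); the duration is then drawn from
#' the component matching the flag.
#'
#' @param main [dist_spec()] for non-adverse patients. Default
#'   Normal(20, 0.5) minutes.
#' @param adverse [dist_spec()] for adverse reactions. Default
#'   20 + exponential(rate = 0.1) minutes.
#' @param adverse_prob Probability of an adverse reaction, default 0.02.
#' @return An object of class `vax_mixture`.
#' @export
obs_mixture <- function(main = dist_spec("normal", mean = 20, sd = 0.5),
                        adverse = dist_spec("exponential", shift = 20, rate = 0.1),
                        adverse_prob = 0.02) {
  if (!inherits(main, "vax_dist") || !inherits(adverse, "vax_dist")) {
    abort_config("`main` and `adverse` must be `dist_spec()` objects.")
  }
  if (!is_prob(adverse_prob)) {
    abort_config("`adverse_prob` must be a probability in [0, 1].")
  }
  structure(
    list(main = main, adverse = adverse, adverse_prob = adverse_prob),
    class = "vax_mixture"
  )
}

#' @export
format.vax_mixture <- function(x, ...) {
  paste0(
    format(x$main), " | adverse(p = ", x$adverse_prob, "): ",
    format(x$adverse)
  )
}

#' @export
print.vax_mixture <- function(x, ...) {
  cat("<observation mixture> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Sample observation times and adverse-reaction flags
#'
#' @param mix An [obs_mixture()].
#' @param n Number of patients.
#' @return A tibble with columns `duration` (minutes) and `adverse`
#'   (logical), one row per patient.
#' @export
sample_observation <- function(mix, n) {
  if (!inherits(mix, "vax_mixture")) {
    abort_config("`mix` must be an `obs_mixture()` object.")
  }
  if (!is_count(n)) abort_domain("`n` must be a non-negative integer count.")
  adverse <- runif(n) < mix$adverse_prob
  duration <- numeric(n)
  duration[!adverse] <- sample_service_times(mix$main, sum(!adverse))
  duration[adverse] <- sample_service_times(mix$adverse, sum(adverse))
  tibble(duration = duration, adverse = adverse)
}
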