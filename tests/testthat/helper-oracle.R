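# Independent discrete-event FCFS simulator, used only as an oracle.
# Maintains an explicit event clock, idle-server set and FIFO waiting line —
# a deliberately different mechanism from the package's vectorised
# next-free-server assignment.
oracle_queue <- function(arrivals, services, n_servers) {
  n <- length(arrivals)
  start <- rep(NA_real_, n)
  depart <- rep(NA_real_, n)
  busy <- rep(FALSE, n_servers)
  cust <- rep(NA_integer_, n_servers)
  done <- rep(Inf, n_servers)
  waiting <- integer(0)
  next_arr <- 1L
  while (next_arr <= n || any(busy)) {
    t_arr <- if (next_arr <= n) arrivals[next_arr] else Inf
    t_dep <- min(done)
    if (t_arr <= t_dep) {
      clock <- t_arr
      waiting <- c(waiting, next_arr)
      next_arr <- next_arr + 1L
    } else {
      clock <- t_dep
      s <- which.min(done)
      depart[cust[s]] <- clock
      busy[s] <- FALSE
      done[s] <- Inf
      cust[s] <- NA_integer_
    }
    while (length(waiting) > 0 && any(!busy)) {
      s <- which(!busy)[1]
      i <- waiting[1]
      waiting <- waiting[-1]
      start[i] <- clock
      busy[s] <- TRUE
      cust[s] <- i
      done[s] <- clock + services[i]
    }
  }
  list(start = start, departure = depart)
}

# Erlang-C closed form: mean queueing delay in an M/M/c system.
erlang_c_wq <- function(lambda, mu, c) {
  a <- lambda / mu
  rho <- a / c
  stopifnot(rho < 1)
  k <- 0:(c - 1)
  block <- a^c / (factorial(c) * (1 - rho))
  p_wait <- block / (sum(a^k / factorial(k)) + block)
  p_wait / (c * mu - lambda)
}
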