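# Independent oracles for engine correctness: M/M/1 and M/M/c (Erlang C)
# closed-form mean queue waits, and a brute-force chronological single-server
# simulator for exact non-preemptive priority/FIFO semantics.

#' Closed-form M/M/1 mean queue wait
#'
#' `Wq = lambda / (mu * (mu - lambda))` for a single exponential server with
#' Poisson arrivals; requires stability (`lam < mu`).
#'
#' @param lam arrival rate per minute.
#' @param mu service rate per minute.
#' @return mean wait in queue, minutes.
#' @export
mm1_mean_wait <- function(lam, mu) {
  if (lam < 0 || mu <= 0) stop("mm1_mean_wait: need lam >= 0, mu > 0")
  if (lam >= mu) stop("mm1_mean_wait: unstable queue (lam >= mu)")
  lam / (mu * (mu - lam))
}

#' Erlang-C mean queue wait for M/M/c
#'
#' Waiting probability from the Erlang-C formula times the conditional mean
#' wait `1/(c*mu - lam)`. Reduces to [mm1_mean_wait()] at `c = 1`.
#'
#' @param lam arrival rate per minute.
#' @param mu per-server service rate per minute.
#' @param c number of servers (integer >= 1).
#' @return mean wait in queue, minutes.
#' @export
mmc_mean_wait <- function(lam, mu, c) {
  if (lam < 0 || mu <= 0 || c < 1 || c != floor(c))
    stop("mmc_mean_wait: need lam >= 0, mu > 0, integer c >= 1")
  if (lam >= c * mu) stop("mmc_mean_wait: unstable queue (lam >= c*mu)")
  a <- lam / mu
  rho <- a / c
  s <- sum(a^(0:(c - 1)) / factorial(0:(c - 1)))
  top <- a^c / (factorial(c) * (1 - rho))
  erlang_c <- top / (s + top)
  erlang_c / (c * mu - lam)
}

#' Brute-force single-server waits
#'
#' Direct chronological stepping of a single-unit, non-preemptive resource:
#' when the server frees, the waiting job with the lowest priority value is
#' served next, ties broken by arrival time then input order. Independent of
#' the event-calendar engine; used as the exact oracle for the engine's
#' priority and FIFO semantics.
#'
#' @param arrival_times,service_times numeric vectors of equal length.
#' @param priorities integer vector (lower = served first); defaults to all
#'   equal.
#' @return numeric vector of per-job waits (start - arrival), in input order.
#' @examples
#' brute_force_waits(c(0, 1), c(5, 5))              # waits 0, 4
#' @export
brute_force_waits <- function(arrival_times, service_times,
                              priorities = rep(0L, length(arrival_times))) {
  n <- length(arrival_times)
  stopifnot(length(service_times) == n, length(priorities) == n)
  if (n == 0) return(numeric(0))
  waits <- numeric(n)
  served <- logical(n)
  free_at <- 0
  for (step in seq_len(n)) {
    t <- max(free_at, min(arrival_times[!served]))
    cand <- which(!served & arrival_times <= t)
    o <- order(priorities[cand], arrival_times[cand], cand)
    j <- cand[o[1]]
    waits[j] <- t - arrival_times[j]
    free_at <- t + service_times[j]
    served[j] <- TRUE
  }
  waits
}

#' Validate the engine against queueing theory
#'
#' Runs the simulation kernel on M/M/1 and M/M/2 systems at several traffic
#' intensities and compares the simulated mean queue wait to the closed
#' forms, and checks exact agreement with [brute_force_waits()] on randomized
#' small scripted instances. The Monte-Carlo band is three standard errors
#' estimated by batch means.
#'
#' @param horizon simulated minutes per queueing run.
#' @param rhos traffic intensities to test.
#' @param n_instances randomized brute-force instances.
#' @param seed root seed.
#' @return data.frame with one row per check: name, value, target, band,
#'   pass.
#' @export
validate_engine <- function(horizon = 1e5, rhos = c(0.3, 0.6, 0.9),
                            n_instances = 100, seed = 1L) {
  out <- list()
  for (c_srv in c(1L, 2L)) {
    for (rho in rhos) {
      lam <- rho * c_srv
      sim <- simulate_mmc(lam, 1, c_srv, horizon, seed = seed)
      target <- mmc_mean_wait(lam, 1, c_srv)
      out[[length(out) + 1]] <- data.frame(
        check = sprintf("M/M/%d rho=%.1f", c_srv, rho),
        value = sim$mean_wait, target = target, band = 3 * sim$se,
        pass = abs(sim$mean_wait - target) <= 3 * sim$se)
    }
  }
  agree <- engine_oracle_agreement(n_instances, seed = seed)
  out[[length(out) + 1]] <- data.frame(
    check = sprintf("oracle agreement (%d instances)", n_instances),
    value = agree$n_agree, target = n_instances, band = 0,
    pass = agree$n_agree == n_instances)
  do.call(rbind, out)
}

#' Simulate an M/M/c queue with the engine
#'
#' Builds a one-resource, one-source model (Poisson arrivals, exponential
#' service) and runs it through [sim_run()]; the standard error of the mean
#' wait is estimated by batch means over arrival order (25 batches) to
#' respect autocorrelation.
#'
#' @param lam,mu,c_srv arrival rate, service rate, servers.
#' @param horizon minutes to simulate.
#' @param seed root seed.
#' @param batches batch count for the standard error.
#' @return list with `mean_wait`, `se`, `n`.
#' @export
simulate_mmc <- function(lam, mu, c_srv, horizon = 1e5, seed = 1L,
                         batches = 25) {
  model <- sim_model(
    resources = list(resource_spec("server", constant_schedule(c_srv), "job")),
    sources = list(arrival_source(
      "jobs", "job",
      pathway(step_seize("server"), step_timeout("service"), step_release()),
      interarrival = 1 / lam)),
    priorities = c(job = 0L),
    durations = list(service = duration_spec("exponential", mean = 1 / mu)))
  log <- sim_run(model, horizon = horizon, seed = seed, scenario = "mmc")
  w <- log$waits[log$waits$completed == TRUE & log$waits$resource == "server", ]
  w <- w[order(w$enqueue_min), ]
  x <- w$wait_min
  n <- length(x)
  b <- max(2, min(batches, n %/% 2))
  grp <- cut(seq_len(n), b, labels = FALSE)
  bm <- tapply(x, grp, mean)
  list(mean_wait = mean(x), se = stats::sd(bm) / sqrt(length(bm)), n = n)
}

#' Exact engine-vs-oracle agreement on random scripted instances
#'
#' Generates small instances (up to 20 jobs, integer arrival times and
#' service durations, mixed priorities), runs each through both the engine
#' (single-unit resource, scripted source) and [brute_force_waits()], and
#' counts instances with exactly equal per-job waits.
#'
#' @param n_instances number of random instances.
#' @param seed seed for instance generation.
#' @param max_jobs maximum jobs per instance.
#' @return list with `n_agree`, `n_instances`, `failures` (indices).
#' @export
engine_oracle_agreement <- function(n_instances = 100, seed = 1L,
                                    max_jobs = 20) {
  set.seed(seed)
  fails <- integer(0)
  for (i in seq_len(n_instances)) {
    n <- sample(2:max_jobs, 1)
    arr <- sort(sample(0:(3 * n), n, replace = TRUE))
    svc <- sample(1:6, n, replace = TRUE)
    pri <- sample(0:2, n, replace = TRUE)
    oracle <- brute_force_waits(arr, svc, pri)
    model <- sim_model(
      resources = list(resource_spec("server", constant_schedule(1), "job")),
      sources = list(arrival_source(
        "jobs", "job",
        pathway(step_seize("server"), step_timeout("service"), step_release()),
        times = arr, priorities = pri)),
      priorities = c(job = 99L),
      durations = list(service = duration_spec("scripted", values = svc)))
    log <- sim_run(model, horizon = max(arr) + sum(svc) + 10, seed = 1L)
    w <- log$waits
    eng <- w$wait_min[order(w$entity_id)]
    if (!(length(eng) == n && isTRUE(all.equal(eng, oracle, tolerance = 1e-12))))
      fails <- c(fails, i)
  }
  list(n_agree = n_instances - length(fails), n_instances = n_instances,
       failures = fails)
}
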