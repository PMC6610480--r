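# Outcome measures computed from event logs: per-patient wait times,
# standardized wait-time densities, resource utilization, scenario deltas
# and the disability-free-life conversion.

#' Wait times from an event log
#'
#' One sample per completed queue_enter -> seize pair in the log, matched per
#' (entity, resource) in chronological order; a patient's wait for a resource
#' is the time spent queueing before the grant. Entities still queued or in
#' service at the horizon (no exit record) are excluded.
#'
#' @param log an `ecr_eventlog` from [sim_run()].
#' @param resource,patient_class optional filters (character vectors).
#' @return a `data.table` with columns replication, entity_id, patient_class,
#'   resource, enqueue_min, wait_min.
#' @export
wait_times <- function(log, resource = NULL, patient_class = NULL) {
  stopifnot(inherits(log, "ecr_eventlog"))
  rec <- log$records
  known_res <- names(log$meta$resources)
  if (!is.null(resource) && !all(resource %in% known_res))
    stop("wait_times: unknown resource(s): ",
         paste(setdiff(resource, known_res), collapse = ", "))
  known_cls <- unique(rec$patient_class)
  if (!is.null(patient_class) && !all(patient_class %in% known_cls))
    stop("wait_times: unknown patient class(es): ",
         paste(setdiff(patient_class, known_cls), collapse = ", "))
  action <- entity_id <- time_min <- k <- seize_min <- wait_min <-
    replication <- enqueue_min <- NULL # data.table NSE
  done <- rec[action == "exit", unique(entity_id)]
  qe <- rec[action == "queue_enter" & entity_id %in% done]
  sz <- rec[action == "seize" & entity_id %in% done]
  data.table::setkey(qe, entity_id, resource, time_min)
  data.table::setkey(sz, entity_id, resource, time_min)
  qe[, k := seq_len(.N), by = c("entity_id", "resource")]
  sz[, k := seq_len(.N), by = c("entity_id", "resource")]
  w <- merge(qe[, list(replication, entity_id, patient_class, resource, k,
                       enqueue_min = time_min)],
             sz[, list(entity_id, resource, k, seize_min = time_min)],
             by = c("entity_id", "resource", "k"))
  w[, wait_min := seize_min - enqueue_min]
  # eager logical indices: bare names inside `[` would bind to the columns
  if (!is.null(resource)) {
    keep <- w$resource %in% resource
    w <- w[keep, ]
  }
  if (!is.null(patient_class)) {
    keep <- w$patient_class %in% patient_class
    w <- w[keep, ]
  }
  w[order(enqueue_min),
    list(replication, entity_id, patient_class, resource, enqueue_min, wait_min)]
}

#' Standardized wait-time density
#'
#' Wait counts are hard to compare across simulations, so waits are expressed
#' as relative probabilities of waiting a given amount of time compared to
#' not waiting at all: the histogram density of strictly positive waits
#' divided by the number of zero-wait patients. Defined only when someone did
#' not wait.
#'
#' @param waits numeric vector of wait times in minutes (or a data frame with
#'   a `wait_min` column).
#' @param binwidth histogram bin width in minutes.
#' @param zero_tol waits at or below this count as "did not wait" (absorbs
#'   floating-point same-instant grants).
#' @return object of class `standardized_density`: a list with `bins` (a
#'   data.frame bin_start, bin_end, density), `n_zero_wait`, `n_waiting`,
#'   `binwidth`.
#' @export
standardized_density <- function(waits, binwidth = 1, zero_tol = 1e-9) {
  if (is.data.frame(waits)) waits <- waits$wait_min
  stopifnot(binwidth > 0)
  n0 <- sum(waits <= zero_tol)
  if (n0 == 0)
    stop("standardized_density: no zero-wait patients; the normalization is ",
         "undefined - compare raw densities instead")
  pos <- waits[waits > zero_tol]
  if (length(pos)) {
    edges <- seq(0, (floor(max(pos) / binwidth) + 1) * binwidth, by = binwidth)
    cnt <- graphics::hist(pos, breaks = edges, plot = FALSE, right = FALSE)$counts
  } else {
    edges <- c(0, binwidth)
    cnt <- 0L
  }
  structure(list(
    bins = data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                      density = cnt / binwidth / n0),
    n_zero_wait = n0, n_waiting = length(pos), binwidth = binwidth),
    class = "standardized_density")
}

#' @export
print.standardized_density <- function(x, ...) {
  cat("<standardized_density>", x$n_waiting, "waiting /", x$n_zero_wait,
      "zero-wait; total standardized mass",
      format(sum(x$bins$density) * x$binwidth, digits = 4), "\n")
  invisible(x)
}

#' Resource utilization from an event log
#'
#' Busy-unit-minutes (integrated over seize/release pairs, services still
#' running at the horizon clipped there) divided by scheduled
#' capacity-minutes over the horizon.
#'
#' @param log an `ecr_eventlog`.
#' @param resource resource name(s); default all.
#' @return data.frame with resource, busy_minutes, capacity_minutes,
#'   utilization.
#' @export
utilization <- function(log, resource = NULL) {
  stopifnot(inherits(log, "ecr_eventlog"))
  res <- log$meta$resources
  if (is.null(resource)) resource <- names(res)
  if (!all(resource %in% names(res)))
    stop("utilization: unknown resource(s): ",
         paste(setdiff(resource, names(res)), collapse = ", "))
  horizon <- log$meta$horizon
  rec <- log$records
  action <- time_min <- NULL
  out <- lapply(resource, function(rn) {
    sz <- rec[action == "seize" & rec$resource == rn, time_min]
    rl <- rec[action == "release" & rec$resource == rn, time_min]
    # every seize contributes -t, every release +t, unfinished services run
    # to the horizon; linearity makes explicit pairing unnecessary
    # (single-unit seizes, as in the ECR model)
    busy <- sum(rl) - sum(sz) + (length(sz) - length(rl)) * horizon
    capmin <- capacity_minutes(res[[rn]]$schedule, horizon)
    if (capmin <= 0) stop("utilization: resource '", rn,
                          "' has zero capacity-minutes")
    data.frame(resource = rn, busy_minutes = busy, capacity_minutes = capmin,
               utilization = busy / capmin)
  })
  do.call(rbind, out)
}

#' Pooled mean wait difference between two scenarios
#'
#' `mean(baseline waits) - mean(scenario waits)` for a resource and patient
#' class, pooled over replications; positive values mean the scenario
#' improved (shortened) waits. Designed for paired runs sharing a root seed
#' (common random numbers).
#'
#' @param scenario_waits,baseline_waits wait tables (data frames with
#'   `wait_min` and `replication`) from [run_replications()] or
#'   [wait_times()], already filtered to the resource/class of interest, or
#'   numeric vectors.
#' @return list with `delta_min` (pooled), `per_replication` (vector of
#'   per-replication mean differences where replication counts match), and
#'   the two pooled means.
#' @export
mean_wait_delta <- function(scenario_waits, baseline_waits) {
  gw <- function(w) if (is.data.frame(w)) w$wait_min else w
  gr <- function(w) if (is.data.frame(w) && "replication" %in% names(w))
    w$replication else NULL
  sw <- gw(scenario_waits); bw <- gw(baseline_waits)
  if (length(sw) == 0 || length(bw) == 0)
    stop("mean_wait_delta: empty wait sample")
  per_rep <- NULL
  sr <- gr(scenario_waits); br <- gr(baseline_waits)
  if (!is.null(sr) && !is.null(br)) {
    if (!setequal(unique(sr), unique(br)))
      warning("mean_wait_delta: replication sets differ; pooled delta only")
    else {
      reps <- sort(unique(br))
      per_rep <- vapply(reps, function(r)
        mean(bw[br == r]) - mean(sw[sr == r]), 0)
      names(per_rep) <- reps
    }
  }
  list(delta_min = mean(bw) - mean(sw),
       baseline_mean = mean(bw), scenario_mean = mean(sw),
       per_replication = per_rep)
}

#' Disability-free life gained from a wait reduction
#'
#' Each minute of earlier ECR treatment buys 4.2 days of disability-free
#' life; the reporting view rounds weeks to the nearest half week. Negative
#' reductions (longer waits) convert to negative days.
#'
#' @param wait_reduction_min reduction in mean wait, minutes.
#' @param days_per_minute conversion rate, default 4.2 days/min.
#' @return list with `days`, `weeks`, `weeks_rounded` (nearest 0.5).
#' @examples
#' disability_free_life(4)   # 16.8 days ~ 2.5 weeks
#' @export
disability_free_life <- function(wait_reduction_min, days_per_minute = 4.2) {
  stopifnot(days_per_minute > 0)
  days <- wait_reduction_min * days_per_minute
  list(days = days, weeks = days / 7, weeks_rounded = round(days / 7 * 2) / 2)
}
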