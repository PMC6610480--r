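# Model-definition layer of the simulation kernel: capacity schedules,
# resources, pathway steps, arrival sources and the assembled sim_model.
# All times are minutes since simulation start; schedules repeat daily.

MINUTES_PER_DAY <- 1440

#' Daily-repeating capacity schedule
#'
#' A step function on the minute-of-day giving the maximum number of
#' simultaneously occupied units of a resource. Segments must tile the day
#' `[0, 1440)` exactly, with integer capacities (0 allowed).
#'
#' @param start,end numeric vectors of segment boundaries in minutes of the
#'   day; segment i covers `[start[i], end[i])`. An `end` of 1440 closes the
#'   day. Segments wrapping midnight must be split by the caller (the
#'   convenience constructors do this).
#' @param capacity integer vector of capacities, one per segment.
#' @return an object of class `capacity_schedule`.
#' @seealso [constant_schedule()], [shift_schedule()], [capacity_at()]
#' @export
capacity_schedule <- function(start, end, capacity) {
  if (length(start) != length(end) || length(start) != length(capacity))
    stop("capacity_schedule: start, end and capacity must have equal length")
  o <- order(start)
  start <- start[o]; end <- end[o]; capacity <- capacity[o]
  if (any(capacity < 0) || any(capacity != floor(capacity)))
    stop("capacity_schedule: capacities must be non-negative integers")
  if (start[1] != 0 || end[length(end)] != MINUTES_PER_DAY ||
      any(start[-1] != end[-length(end)]))
    stop("capacity_schedule: segments must tile [0, 1440) with no gaps or overlaps")
  structure(list(bounds = c(start, MINUTES_PER_DAY), caps = as.integer(capacity)),
            class = "capacity_schedule")
}

#' @rdname capacity_schedule
#' @param cap single integer capacity held around the clock.
#' @export
constant_schedule <- function(cap) {
  capacity_schedule(0, MINUTES_PER_DAY, cap)
}

#' @rdname capacity_schedule
#' @param day_capacity,night_capacity capacities during and outside the day
#'   shift.
#' @param day_start,day_end day-shift boundaries in minutes of the day
#'   (defaults 08:00 and 17:00).
#' @export
shift_schedule <- function(day_capacity, night_capacity,
                           day_start = 480, day_end = 1020) {
  if (day_end <= day_start || day_start < 0 || day_end > MINUTES_PER_DAY)
    stop("shift_schedule: need 0 <= day_start < day_end <= 1440")
  if (day_start == 0) {
    capacity_schedule(c(0, day_end), c(day_end, MINUTES_PER_DAY),
                      c(day_capacity, night_capacity))
  } else if (day_end == MINUTES_PER_DAY) {
    capacity_schedule(c(0, day_start), c(day_start, MINUTES_PER_DAY),
                      c(night_capacity, day_capacity))
  } else {
    capacity_schedule(c(0, day_start, day_end),
                      c(day_start, day_end, MINUTES_PER_DAY),
                      c(night_capacity, day_capacity, night_capacity))
  }
}

#' Scheduled capacity at a simulation time
#'
#' @param schedule a [capacity_schedule()].
#' @param t simulation time(s) in minutes; reduced modulo 1440.
#' @return integer capacity (vectorized over `t`).
#' @examples
#' ir <- shift_schedule(2, 1)      # interventional radiologists
#' capacity_at(ir, 10 * 60)        # 2 during the day shift
#' capacity_at(ir, 3 * 60)         # 1 overnight
#' @export
capacity_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "capacity_schedule"))
  tm <- t %% MINUTES_PER_DAY
  schedule$caps[findInterval(tm, schedule$bounds)]
}

#' Integrated capacity-minutes of a schedule over an interval
#'
#' The time integral of [capacity_at()] over `[from, horizon)`; the
#' denominator of a utilization rate.
#'
#' @param schedule a [capacity_schedule()].
#' @param horizon,from interval bounds in minutes.
#' @return unit-minutes of scheduled capacity.
#' @export
capacity_minutes <- function(schedule, horizon, from = 0) {
  if (horizon <= from) return(0)
  seg_len <- diff(schedule$bounds)
  per_day <- sum(seg_len * schedule$caps)
  integral_to <- function(t) {
    full <- floor(t / MINUTES_PER_DAY)
    tm <- t - full * MINUTES_PER_DAY
    i <- findInterval(tm, schedule$bounds)
    part <- 0
    if (i >= 1) {
      done <- if (i > 1) sum(seg_len[1:(i - 1)] * schedule$caps[1:(i - 1)]) else 0
      part <- done + (tm - schedule$bounds[i]) * schedule$caps[i]
    }
    full * per_day + part
  }
  integral_to(horizon) - integral_to(from)
}

#' Define a resource pool
#'
#' A named pool of interchangeable units (an angiography suite, a CT scanner,
#' a staff group) with a daily capacity schedule and a class-eligibility rule.
#'
#' @param name identifier used by pathway steps and in the event log.
#' @param schedule a [capacity_schedule()].
#' @param eligible_classes character vector of patient classes permitted to
#'   seize this resource; must be non-empty.
#' @param suite logical; marks angiography suites, i.e. resources a
#'   route-choice step may pick between.
#' @param human logical; human pools have their day shift stretched by the
#'   extended-schedule scenario, physical machines do not.
#' @return an object of class `resource_spec`.
#' @export
resource_spec <- function(name, schedule, eligible_classes,
                          suite = FALSE, human = FALSE) {
  stopifnot(inherits(schedule, "capacity_schedule"))
  if (length(eligible_classes) == 0)
    stop("resource_spec '", name, "': eligible_classes must be non-empty")
  structure(list(name = name, schedule = schedule,
                 eligible_classes = unique(eligible_classes),
                 suite = isTRUE(suite), human = isTRUE(human)),
            class = "resource_spec")
}

#' Duration distribution for a service step
#'
#' @param distribution one of `"fixed"`, `"exponential"`, `"lognormal"`,
#'   `"scripted"`.
#' @param mean mean duration in minutes (ignored for `"scripted"`).
#' @param cv coefficient of variation; used by the lognormal only.
#' @param values for `"scripted"`: explicit per-arrival durations, indexed by
#'   the entity's arrival index within its source (test/oracle use).
#' @export
duration_spec <- function(distribution = c("lognormal", "exponential", "fixed", "scripted"),
                          mean = NULL, cv = 0.5, values = NULL) {
  distribution <- match.arg(distribution)
  if (distribution == "scripted") {
    if (is.null(values)) stop("duration_spec: scripted distribution needs values")
  } else {
    if (is.null(mean) || mean <= 0) stop("duration_spec: mean must be > 0")
    if (cv < 0) stop("duration_spec: cv must be >= 0")
  }
  structure(list(distribution = distribution, mean = mean, cv = cv,
                 values = values), class = "duration_spec")
}

# --- pathway steps ---------------------------------------------------------

#' Pathway step constructors
#'
#' A pathway is a finite ordered sequence of steps that an entity executes
#' chronologically: seizing resource bundles (atomically: the entity waits
#' until every member of the bundle has a free unit, holding none meanwhile),
#' timed service, release, probabilistic branching (continue with probability
#' `prob`, otherwise exit), and shortest-queue routing between candidate
#' suites. `step_exit` is appended automatically by [pathway()].
#'
#' @param resources character vector of resource names seized together.
#' @param units integer units per resource (recycled).
#' @param gated logical; a gated seize may only be *granted* between the
#'   model's work-hours window (queueing outside it is allowed) — the
#'   elective service-start rule.
#' @param candidates character vector of suite names to route between by
#'   shortest queue (waiting requests + busy units; ties broken by
#'   declaration order).
#' @param extra resources bundled with the routed suite (physician, staff).
#' @param duration name of a duration in the model's duration table.
#' @param prob name of a branch probability in the model's table.
#' @name pathway_steps
NULL

#' @rdname pathway_steps
#' @export
step_seize <- function(resources, units = 1L, gated = FALSE) {
  list(kind = "seize", resources = resources,
       units = as.integer(rep_len(units, length(resources))), gated = gated)
}

#' @rdname pathway_steps
#' @export
step_route_seize <- function(candidates, extra = character(), units = 1L,
                             gated = FALSE) {
  n <- 1L + length(extra)
  list(kind = "route_seize", candidates = candidates, extra = extra,
       units = as.integer(rep_len(units, n)), gated = gated)
}

#' @rdname pathway_steps
#' @export
step_timeout <- function(duration) list(kind = "timeout", duration = duration)

#' @rdname pathway_steps
#' @export
step_release <- function() list(kind = "release")

#' @rdname pathway_steps
#' @export
step_branch <- function(prob) list(kind = "branch", prob = prob)

#' @rdname pathway_steps
#' @export
pathway <- function(...) {
  steps <- list(...)
  structure(c(steps, list(list(kind = "exit"))), class = "ecr_pathway")
}

#' Arrival source
#'
#' Either a Poisson stream (`interarrival` = mean gap in minutes) or a
#' scripted list of arrival times. Scripted sources may carry per-arrival
#' priorities, overriding the class priority (oracle tests).
#'
#' @param name stream identifier (also names its random stream).
#' @param patient_class class label of generated entities.
#' @param pathway a [pathway()].
#' @param interarrival mean interarrival gap in minutes; `Inf` for a silent
#'   source.
#' @param times explicit arrival times (minutes), overrides `interarrival`.
#' @param priorities optional per-arrival priority vector for scripted times.
#' @export
arrival_source <- function(name, patient_class, pathway, interarrival = NULL,
                           times = NULL, priorities = NULL) {
  if (is.null(times) && is.null(interarrival))
    stop("arrival_source '", name, "': give interarrival or times")
  if (!is.null(interarrival) && !is.null(times))
    stop("arrival_source '", name, "': give only one of interarrival/times")
  if (!is.null(interarrival) && interarrival <= 0)
    stop("arrival_source '", name, "': interarrival must be > 0 (use Inf to silence)")
  if (!is.null(priorities) && is.null(times))
    stop("arrival_source '", name, "': per-arrival priorities need scripted times")
  structure(list(name = name, patient_class = patient_class,
                 pathway = pathway, interarrival = interarrival,
                 times = times, priorities = priorities),
            class = "arrival_source")
}

#' Assemble a simulation model
#'
#' Binds resources, arrival sources, the class-priority map, duration and
#' branch-probability tables and the elective work-hours window into the
#' object [sim_run()] executes. All cross-references (step resource names,
#' duration names, branch names, class eligibility) are validated here.
#'
#' @param resources list of [resource_spec()].
#' @param sources list of [arrival_source()].
#' @param priorities named integer vector, patient class -> priority
#'   (lower = more urgent).
#' @param durations named list of [duration_spec()].
#' @param branch_probs named numeric vector of probabilities in `[0,1]`.
#' @param gate_window length-2 numeric, minutes of day between which gated
#'   (elective) seizes may start service.
#' @return an object of class `sim_model`.
#' @export
sim_model <- function(resources, sources, priorities,
                      durations = list(), branch_probs = numeric(),
                      gate_window = c(480, 1020)) {
  if (length(resources) == 0) stop("sim_model: need at least one resource")
  if (length(sources) == 0) stop("sim_model: need at least one arrival source")
  rnames <- vapply(resources, function(r) r$name, "")
  if (anyDuplicated(rnames)) stop("sim_model: duplicate resource names")
  names(resources) <- rnames
  snames <- vapply(sources, function(s) s$name, "")
  if (anyDuplicated(snames)) stop("sim_model: duplicate source names")
  names(sources) <- snames
  if (any(branch_probs < 0 | branch_probs > 1))
    stop("sim_model: branch probabilities must lie in [0,1]")

  for (src in sources) {
    cls <- src$patient_class
    if (!cls %in% names(priorities))
      stop("sim_model: no priority defined for class '", cls, "'")
    for (st in src$pathway) {
      req <- switch(st$kind, seize = st$resources,
                    route_seize = c(st$candidates, st$extra), character())
      missing <- setdiff(req, rnames)
      if (length(missing))
        stop("sim_model: pathway of '", src$name,
             "' references unknown resource(s): ",
             paste(missing, collapse = ", "))
      for (rn in req) {
        if (!cls %in% resources[[rn]]$eligible_classes)
          stop("sim_model: class '", cls, "' is not eligible for resource '",
               rn, "' (pathway of '", src$name, "')")
      }
      if (st$kind == "timeout" && !st$duration %in% names(durations))
        stop("sim_model: unknown duration '", st$duration, "'")
      if (st$kind == "branch" && !st$prob %in% names(branch_probs))
        stop("sim_model: unknown branch probability '", st$prob, "'")
      if (st$kind %in% c("seize", "route_seize")) {
        nm <- if (st$kind == "seize") st$resources else c(st$candidates, st$extra)
        un <- if (st$kind == "seize") st$units
              else c(rep(st$units[1], length(st$candidates)), st$units[-1])
        maxcap <- vapply(nm, function(rn) max(resources[[rn]]$schedule$caps), 0L)
        if (any(un > maxcap))
          stop("sim_model: requested units exceed maximum scheduled capacity of ",
               paste(nm[un > maxcap], collapse = ", "))
      }
      if (st$kind == "route_seize" && length(st$candidates) == 0)
        stop("sim_model: empty candidate set in route step of '", src$name, "'")
    }
  }
  structure(list(resources = resources, sources = sources,
                 priorities = priorities, durations = durations,
                 branch_probs = branch_probs, gate_window = gate_window),
            class = "sim_model")
}

# Deterministic 31-bit sub-seed from a root seed and a stream name.
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(bitwXor(as.integer(seed %% 2147483647), as.integer(h)))
}
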