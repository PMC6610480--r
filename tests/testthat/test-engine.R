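# Simulation kernel: schedules, priority queues, atomic bundle seizure,
# shift-change semantics, determinism, conservation.

test_that("capacity schedules follow the shift table and validate tiling", {
  ir <- shift_schedule(2, 1)
  expect_equal(capacity_at(ir, 10 * 60), 2)          # 10:00, day shift
  expect_equal(capacity_at(ir, 3 * 60), 1)           # 03:00, night
  expect_equal(capacity_at(ir, 3 * 60 + 5 * 1440), 1)  # repeats daily
  expect_equal(capacity_at(constant_schedule(1), 123456), 1)
  # boundaries belong to the opening segment
  expect_equal(capacity_at(ir, 480), 2)
  expect_equal(capacity_at(ir, 1020), 1)

  expect_error(capacity_schedule(c(0, 500), c(480, 1440), c(1, 2)),
               "tile")                               # overlap
  expect_error(capacity_schedule(c(0, 500), c(480, 1440), c(1, 2)), "tile")
  expect_error(capacity_schedule(0, 1440, -1), "non-negative")
  expect_error(capacity_schedule(0, 1200, 1), "tile")  # day not closed

  # capacity-minutes integral over one and a half days
  expect_equal(capacity_minutes(ir, 1440), 540 * 2 + 900 * 1)
  expect_equal(capacity_minutes(ir, 1440 + 720),
               (540 * 2 + 900) + 480 + 240 * 2)
})

test_that("an empty system produces an empty log", {
  m <- sim_model(
    resources = list(resource_spec("server", constant_schedule(1), "job")),
    sources = list(arrival_source(
      "jobs", "job",
      pathway(step_seize("server"), step_timeout("svc"), step_release()),
      interarrival = Inf)),
    priorities = c(job = 0L),
    durations = list(svc = duration_spec("fixed", mean = 1)))
  log <- sim_run(m, horizon = 10000, seed = 1)
  expect_equal(nrow(log$records), 0)
  expect_equal(nrow(log$waits), 0)
  expect_equal(log$utilization$busy_minutes, 0)
})

test_that("identical seeds reproduce byte-identical logs, different seeds differ", {
  m <- build_model(fast_params())
  a <- sim_run(m, horizon = 20 * 1440, seed = 11)
  b <- sim_run(m, horizon = 20 * 1440, seed = 11)
  expect_identical(a$records, b$records)
  expect_identical(a$waits, b$waits)
  c <- sim_run(m, horizon = 20 * 1440, seed = 12)
  expect_false(identical(a$records, c$records))
})

test_that("a stroke and an emergency IR patient jump a queue of 10 electives", {
  # occupant in service, then 10 elective arrivals, then one stroke (priority
  # 0) and one emergency IR (priority 1): service order after the occupant
  # must be stroke, emergency IR, then the electives in FIFO order
  m <- single_server_model(
    times = 0:12,
    services = c(200, rep(5, 10), 30, 20),
    priorities = c(2, rep(2, 10), 0, 1))
  log <- sim_run(m, horizon = 500, seed = 1)
  expect_equal(seize_order(log, "server"), c(1L, 12L, 13L, 2:11))
})

test_that("equal-priority requests are served FIFO, handoff at the same instant", {
  m <- single_server_model(times = c(0, 1), services = c(5, 5))
  log <- sim_run(m, horizon = 100, seed = 1)
  w <- log$waits[order(log$waits$entity_id), ]
  expect_equal(w$wait_min, c(0, 4))
  rec <- log$records
  rel1 <- rec$time_min[rec$entity_id == 1 & rec$action == "release"]
  sz2 <- rec$time_min[rec$entity_id == 2 & rec$action == "seize"]
  expect_equal(sz2, rel1)   # release re-examines the queue immediately
})

test_that("a capacity drop below the busy count blocks new grants, not services", {
  # day capacity 2 (08:00-17:00), night 1; two services straddle 17:00, a
  # third job arrives at night: it may only start once busy < night capacity
  m <- single_server_model(times = c(1000, 1005, 1030),
                           services = c(100, 145, 10),
                           schedule = shift_schedule(2, 1))
  log <- sim_run(m, horizon = 2000, seed = 1)
  rec <- log$records
  sz <- rec$time_min[rec$action == "seize"]
  expect_equal(sz, c(1000, 1005, 1150))
  # in-progress services completed normally past the 17:00 change
  expect_equal(rec$time_min[rec$action == "release"], c(1100, 1150, 1160))
  w <- log$waits[log$waits$entity_id == 3, ]
  expect_equal(w$wait_min, 120)
})

test_that("bundle seizure is atomic and priority inserts ahead of a blocked head", {
  # r1 busy to t=50, r2 busy to t=30. A bundle {r1,r2} request (priority 2)
  # waits from t=5 holding nothing; an urgent r2-only request at t=31 takes
  # the free r2 ahead of the blocked bundle head; bundle starts at t=50.
  m <- sim_model(
    resources = list(resource_spec("r1", constant_schedule(1), c("a", "c")),
                     resource_spec("r2", constant_schedule(1), c("b", "c", "d"))),
    sources = list(
      arrival_source("h1", "a", pathway(step_seize("r1"),
                                        step_timeout("s50"), step_release()),
                     times = 0),
      arrival_source("h2", "b", pathway(step_seize("r2"),
                                        step_timeout("s30"), step_release()),
                     times = 0),
      arrival_source("bundle", "c",
                     pathway(step_seize(c("r1", "r2")),
                             step_timeout("s30"), step_release()),
                     times = 5),
      arrival_source("urgent", "d", pathway(step_seize("r2"),
                                            step_timeout("s5"), step_release()),
                     times = 31)),
    priorities = c(a = 2L, b = 2L, c = 2L, d = 0L),
    durations = list(s50 = duration_spec("fixed", mean = 50),
                     s30 = duration_spec("fixed", mean = 30),
                     s5 = duration_spec("fixed", mean = 5)))
  log <- sim_run(m, horizon = 200, seed = 1)
  w <- log$waits
  expect_equal(w$wait_min[w$patient_class == "d"], 0)          # free r2 taken
  expect_equal(unique(w$wait_min[w$patient_class == "c"]), 45) # granted at 50
  sz <- w$enqueue_min[w$patient_class == "c"] + w$wait_min[w$patient_class == "c"]
  expect_equal(unique(sz), 50)
  # no partial holding: r2 busy-minutes = 30 (h2) + 5 (urgent) + 30 (bundle)
  u <- log$utilization
  expect_equal(u$busy_minutes[u$resource == "r2"], 65)
})

test_that("route choice picks the least-occupied suite, ties by declaration order", {
  mk <- function(times_s1_direct, router_time) sim_model(
    resources = list(resource_spec("s1", constant_schedule(1), c("x", "r"), suite = TRUE),
                     resource_spec("s2", constant_schedule(1), c("x", "r"), suite = TRUE)),
    sources = list(
      arrival_source("occ1", "x", pathway(step_seize("s1"),
                                          step_timeout("long"), step_release()),
                     times = times_s1_direct),
      arrival_source("occ2", "x", pathway(step_seize("s2"),
                                          step_timeout("long"), step_release()),
                     times = 0),
      arrival_source("router", "r",
                     pathway(step_route_seize(c("s1", "s2")),
                             step_timeout("short"), step_release()),
                     times = router_time)),
    priorities = c(x = 1L, r = 1L),
    durations = list(long = duration_spec("fixed", mean = 100),
                     short = duration_spec("fixed", mean = 1)))
  # s1 occupancy 3 (1 busy + 2 queued), s2 occupancy 1 -> route to s2
  log <- sim_run(mk(c(0, 1, 2), 5), horizon = 400, seed = 1)
  rec <- log$records
  router_id <- max(rec$entity_id)
  expect_equal(rec$resource[rec$entity_id == router_id &
                            rec$action == "queue_enter"], "s2")
  # both idle (equal occupancy 0): first declared wins
  m2 <- sim_model(
    resources = list(resource_spec("s1", constant_schedule(1), "r", suite = TRUE),
                     resource_spec("s2", constant_schedule(1), "r", suite = TRUE)),
    sources = list(arrival_source("router", "r",
                                  pathway(step_route_seize(c("s1", "s2")),
                                          step_timeout("short"), step_release()),
                                  times = 0)),
    priorities = c(r = 1L),
    durations = list(short = duration_spec("fixed", mean = 1)))
  log2 <- sim_run(m2, horizon = 10, seed = 1)
  expect_equal(log2$records$resource[log2$records$action == "seize"], "s1")
})

test_that("model validation names unknown resources and ineligible classes", {
  r <- list(resource_spec("server", constant_schedule(1), "job"))
  p <- pathway(step_seize("missing"), step_timeout("svc"), step_release())
  expect_error(
    sim_model(r, list(arrival_source("s", "job", p, interarrival = 10)),
              priorities = c(job = 0L),
              durations = list(svc = duration_spec("fixed", mean = 1))),
    "missing")
  p2 <- pathway(step_seize("server"), step_timeout("svc"), step_release())
  expect_error(
    sim_model(r, list(arrival_source("s", "alien", p2, interarrival = 10)),
              priorities = c(alien = 0L),
              durations = list(svc = duration_spec("fixed", mean = 1))),
    "not eligible")
})

test_that("conservation holds: seize/release pairing and capacity never exceeded", {
  m <- build_model(fast_params())
  for (seed in c(101, 202)) {
    log <- sim_run(m, horizon = 20 * 1440, seed = seed)
    rec <- log$records
    done <- rec$entity_id[rec$action == "exit"]
    per <- rec[rec$entity_id %in% done & rec$action %in% c("seize", "release"),
               .N, by = c("entity_id", "resource", "action")]
    wide <- data.table::dcast(per, entity_id + resource ~ action,
                              value.var = "N", fill = 0L)
    expect_true(all(wide$seize == wide$release))
    # busy units never exceed the scheduled capacity at the grant instant
    for (rn in names(log$meta$resources)) {
      ev <- rec[rec$resource == rn & rec$action %in% c("seize", "release"), ]
      if (nrow(ev) == 0) next
      delta <- ifelse(ev$action == "seize", 1L, -1L)
      busy <- cumsum(delta)
      expect_true(all(busy >= 0))
      grants <- which(delta == 1L)
      cap <- capacity_at(log$meta$resources[[rn]]$schedule, ev$time_min[grants])
      expect_true(all(busy[grants] <= cap),
                  label = paste("capacity respected at", rn))
    }
  }
})

test_that("priority safety and FIFO-within-class hold at the biplane suite", {
  log <- sim_run(build_model(fast_params()), horizon = 60 * 1440, seed = 77)
  w <- wait_times(log, resource = "angio_inr")
  pr <- c(stroke = 0L, emergency_ir = 1L, elective_inr = 2L, elective_ir = 2L)
  w$prio <- pr[w$patient_class]
  w$grant <- w$enqueue_min + w$wait_min
  # no grant while a strictly-higher-priority request was already waiting
  for (i in seq_len(nrow(w))) {
    waiting <- w$enqueue_min < w$grant[i] & w$grant > w$grant[i]
    expect_true(all(w$prio[waiting] >= w$prio[i]))
  }
  # FIFO within equal priority: grant order equals enqueue order
  for (p in unique(w$prio)) {
    g <- w[w$prio == p, ]
    g <- g[order(g$enqueue_min), ]
    expect_true(!is.unsorted(g$grant))
  }
})
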