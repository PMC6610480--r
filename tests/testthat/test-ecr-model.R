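# The ECR service model: derived rates, branch probabilities, default
# resources, pathway structure and arrival processes.

test_that("interarrival times derive from annual counts over 525,600 min", {
  expect_equal(derive_interarrival(3805, rounded = TRUE), 138)
  expect_equal(derive_interarrival(58, rounded = TRUE), 9062)
  expect_equal(derive_interarrival(468, rounded = TRUE), 1123)
  expect_equal(derive_interarrival(750, rounded = TRUE), 701)
  expect_equal(derive_interarrival(104, rounded = TRUE), 5054)
  expect_equal(derive_interarrival(107700, rounded = TRUE), 5)
  expect_equal(derive_interarrival(525600), 1)
  expect_equal(derive_interarrival(58), 525600 / 58)   # exact internally
  expect_error(derive_interarrival(0), "positive")
  expect_error(derive_interarrival(-5), "positive")
})

test_that("funnel branch probabilities are ratios of nested annual counts", {
  bp <- derive_branch_probs(default_annual_counts())
  expect_equal(unname(bp["p_ais"]), 0.600)
  expect_equal(unname(bp["p_ecr"]), 58 / 450)
  expect_equal(unname(bp["p_suspected"]), 750 / 107700)
  # degenerate funnel: every AIS goes to ECR
  bp2 <- derive_branch_probs(c(ed = 100, suspected_stroke = 50, ais = 20,
                               ecr = 20))
  expect_equal(unname(bp2["p_ecr"]), 1)
  expect_error(derive_branch_probs(c(ed = 10, suspected_stroke = 20,
                                     ais = 5, ecr = 1)), "funnel")
})

test_that("default resources match the shipped capacity table", {
  r <- default_resources()
  expect_equal(capacity_at(r$ir$schedule, 9 * 60), 2)          # 09:00
  expect_equal(capacity_at(r$ir$schedule, 3 * 60), 1)
  expect_equal(capacity_at(r$angio_staff$schedule, 2 * 60), 3) # 02:00
  expect_equal(capacity_at(r$angio_staff$schedule, 12 * 60), 6)
  expect_equal(capacity_at(r$ct$schedule, 1234), 2)
  expect_equal(capacity_at(r$inr$schedule, 1234), 1)
  expect_equal(capacity_at(r$angio_inr$schedule, 0), 1)
  expect_equal(capacity_at(r$ed_team$schedule, 0), 10)
  expect_equal(capacity_at(r$stroke_team$schedule, 0), 1)
  expect_true(r$angio_inr$suite && r$angio_ir$suite && !r$ct$suite)
  # baseline eligibility: the single-plane suite takes IR work only
  expect_setequal(r$angio_ir$eligible_classes, c("emergency_ir", "elective_ir"))
  expect_true("elective_ir" %in% r$angio_inr$eligible_classes)
})

test_that("the built model has the funnel sources, gate and priorities", {
  m <- build_model(fast_params())
  expect_setequal(names(m$sources),
                  c("suspected_stroke", "elective_inr", "emergency_ir",
                    "elective_ir"))
  expect_equal(m$gate_window, c(480, 1020))
  expect_equal(m$sources$suspected_stroke$interarrival, 525600 / 750)
  pr <- m$priorities
  expect_true(pr[["stroke"]] < pr[["emergency_ir"]])
  expect_true(pr[["emergency_ir"]] < pr[["elective_inr"]])
  expect_true(pr[["emergency_ir"]] < pr[["elective_ir"]])
  # background ED stream present when enabled
  m2 <- build_model(ecr_params(ed_background = TRUE))
  expect_true("ed_other" %in% names(m2$sources))
  expect_equal(m2$sources$ed_other$interarrival, 525600 / (107700 - 750))
})

test_that("Poisson arrivals reproduce the annual counts and scale with demand", {
  run <- run_replications(fast_params(), "baseline", horizon_days = 120,
                          replications = 5, seed = 31)
  f <- 120 / 365
  cnt <- run$counts
  for (s in c("suspected_stroke", "elective_inr", "emergency_ir",
              "elective_ir")) {
    N <- default_annual_counts()[[s]] * f
    m <- mean(cnt$arrivals[cnt$source == s])
    expect_lt(abs(m - N), 3 * sqrt(N / 5) + 1e-9, label = paste("count", s))
  }
  # demand doubling scales the stroke funnel but not the elective streams
  run2 <- run_replications(fast_params(), "demand:2", horizon_days = 120,
                           replications = 5, seed = 31)
  cnt2 <- run2$counts
  m2 <- mean(cnt2$arrivals[cnt2$source == "suspected_stroke"])
  expect_lt(abs(m2 - 2 * 750 * f), 3 * sqrt(2 * 750 * f / 5))
  m3 <- mean(cnt2$arrivals[cnt2$source == "elective_ir"])
  expect_lt(abs(m3 - 3805 * f), 3 * sqrt(3805 * f / 5))
})

test_that("a zeroed stream generates no arrivals", {
  p <- fast_params(annual_counts = c(elective_inr = 0))
  log <- sim_run(build_model(p), horizon = 60 * 1440, seed = 5)
  expect_false("elective_inr" %in% log$counts$source)
  expect_false(any(log$records$patient_class == "elective_inr"))
})

test_that("baseline eligibility keeps stroke and elective INR off the single-plane suite", {
  log <- sim_run(build_model(fast_params()), horizon = 60 * 1440, seed = 9)
  rec <- log$records
  at_ir <- rec[rec$resource == "angio_ir", ]
  expect_false(any(at_ir$patient_class %in% c("stroke", "elective_inr")))
  # elective INR patients always queue at the biplane suite
  einr <- rec[rec$patient_class == "elective_inr" & rec$action == "queue_enter", ]
  expect_setequal(unique(einr$resource), c("angio_staff", "angio_inr", "inr"))
})

test_that("the funnel delivers ~58 ECR-treated patients per simulated year", {
  run <- run_replications(fast_params(), "baseline", horizon_days = 365,
                          replications = 3, seed = 13)
  w <- ecr_suite_waits(run)
  per_rep <- tapply(w$entity_id, w$replication, length)
  expect_lt(abs(mean(per_rep) - 58), 3 * sqrt(58 / 3))
})

test_that("the independent-streams construction reproduces the same funnel rows", {
  p <- fast_params(arrivals_mode = "independent")
  m <- build_model(p)
  expect_setequal(names(m$sources),
                  c("suspected_non_ais", "ais_non_ecr", "ecr",
                    "elective_inr", "emergency_ir", "elective_ir"))
  expect_equal(m$sources$ecr$interarrival, 525600 / 58)
  expect_equal(m$sources$ais_non_ecr$interarrival, 525600 / (450 - 58))
  log <- sim_run(m, horizon = 365 * 1440, seed = 21)
  n_ecr <- nrow(log$waits[log$waits$resource == "angio_inr" &
                          log$waits$patient_class == "stroke", ])
  expect_lt(abs(n_ecr - 58), 3 * sqrt(58))
})
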