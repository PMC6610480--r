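# Shared fixtures: all built in code at test time.

# One single-unit server, one scripted job stream (the oracle-comparable
# instance shape).
single_server_model <- function(times, services, priorities = NULL,
                                capacity = 1, schedule = NULL) {
  sim_model(
    resources = list(resource_spec(
      "server", schedule %||ecr% constant_schedule(capacity), "job")),
    sources = list(arrival_source(
      "jobs", "job",
      pathway(step_seize("server"), step_timeout("service"), step_release()),
      times = times, priorities = priorities)),
    priorities = c(job = 5L),
    durations = list(service = duration_spec("scripted", values = services)))
}

`%||ecr%` <- function(a, b) if (is.null(a)) b else a

# Fast baseline parameters: the shipped world minus the background ED stream
# (ED-team offered load ~0.31 on 10 servers; see the methods vignette).
fast_params <- function(...) ecr_params(ed_background = FALSE, ...)

seize_order <- function(log, resource) {
  r <- log$records
  r$entity_id[r$action == "seize" & r$resource == resource]
}

# Acceptance-scale runs (30 reps x 365 days) are expensive; compute each arm
# once per test session and share across test files.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(scenario, seed = 20260917L, replications = 30) {
  key <- paste0(scenario, "_", seed, "_", replications)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_replications(
      fast_params(), scenario = scenario, horizon_days = 365,
      replications = replications, seed = seed)
  }
  .run_cache[[key]]
}
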