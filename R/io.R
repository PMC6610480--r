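# Configuration loading/validation, replication orchestration, summaries,
# scenario comparison and serialization. The command-line entry point
# (inst/cli/ecr-des.R) is a thin wrapper over these functions.

#' Derived model-input table
#'
#' Reproduces the shipped input table from the annual counts: the mean
#' interarrival time of every patient stream (exact and rounded to whole
#' minutes), the funnel branch probabilities, and the elective-IR to ECR
#' volume ratio.
#'
#' @param params an [ecr_params()]; defaults ship in-package.
#' @return object of class `table1_derivation`: list with `streams` (a
#'   data.frame), `branch_probs`, `elective_ir_to_ecr_ratio`.
#' @export
derive_table1 <- function(params = ecr_params()) {
  ac <- params$annual_counts
  streams <- data.frame(
    stream = names(ac),
    annual_count = as.numeric(ac),
    interarrival_exact_min = derive_interarrival(as.numeric(ac)),
    interarrival_min = derive_interarrival(as.numeric(ac), rounded = TRUE))
  structure(list(
    streams = streams,
    branch_probs = params$branch_probs,
    elective_ir_to_ecr_ratio = floor(ac[["elective_ir"]] / ac[["ecr"]])),
    class = "table1_derivation")
}

#' @export
print.table1_derivation <- function(x, ...) {
  cat("Derived patient streams (525,600 min/year):\n")
  print(x$streams, row.names = FALSE)
  cat("\nFunnel branch probabilities:\n")
  print(round(x$branch_probs, 4))
  cat("\nElective IR : ECR volume ratio (floor):",
      x$elective_ir_to_ecr_ratio, "\n")
  invisible(x)
}

#' Run replications of a scenario
#'
#' Applies `scenario` to the baseline parameters, builds the model and runs
#' `replications` independent replications; replication `r` uses root seed
#' `xor(seed, r)`, so paired scenario runs with the same `seed` share random
#' streams (common random numbers).
#'
#' @param params baseline [ecr_params()].
#' @param scenario scenario spec string for [apply_scenario()].
#' @param horizon_days simulated days per replication.
#' @param replications number of replications.
#' @param seed integer root seed.
#' @param warmup_days waits enqueued before this are dropped from the pooled
#'   wait table (utilization is always integrated over the full horizon).
#' @param out_dir if given, per-replication event logs are written here as
#'   CSV when `event_log = TRUE`.
#' @param event_log write per-replication event-log CSVs?
#' @param progress print a dot per replication?
#' @return object of class `ecr_run`: list with `waits` (pooled completed
#'   waits), `utilization` (per replication x resource), `counts` (arrivals
#'   per replication x source) and `meta`.
#' @export
run_replications <- function(params, scenario = "baseline",
                             horizon_days = 365, replications = 30,
                             seed = 1L, warmup_days = 0,
                             out_dir = NULL, event_log = FALSE,
                             progress = FALSE) {
  stopifnot(inherits(params, "ecr_params"))
  if (replications < 1) stop("run_replications: replications must be >= 1")
  if (warmup_days < 0 || warmup_days >= horizon_days)
    stop("run_replications: need horizon_days > warmup_days >= 0")
  p2 <- apply_scenario(params, scenario)
  model <- build_model(p2)
  horizon <- horizon_days * 1440
  warmup <- warmup_days * 1440
  waits <- vector("list", replications)
  util <- vector("list", replications)
  counts <- vector("list", replications)
  for (r in seq_len(replications)) {
    rep_seed <- bitwXor(as.integer(seed), as.integer(r))
    log <- sim_run(model, horizon = horizon, seed = rep_seed,
                   replication = r, scenario = scenario)
    w <- log$waits[log$waits$completed & log$waits$enqueue_min >= warmup, ]
    w$completed <- NULL
    waits[[r]] <- w
    util[[r]] <- log$utilization
    counts[[r]] <- log$counts
    if (event_log && !is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_eventlog_csv(log, file.path(out_dir,
                                        sprintf("events_rep%03d.csv", r)))
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(
    waits = data.table::rbindlist(waits),
    utilization = data.table::rbindlist(util),
    counts = data.table::rbindlist(counts),
    meta = list(scenario = scenario, horizon_days = horizon_days,
                replications = replications, seed = seed,
                warmup_days = warmup_days, params = p2)),
    class = "ecr_run")
}

#' @export
print.ecr_run <- function(x, ...) {
  cat("<ecr_run>", x$meta$scenario, "-", x$meta$replications, "reps x",
      x$meta$horizon_days, "days (seed", paste0(x$meta$seed, ")"), "\n")
  cat("  pooled completed waits:", nrow(x$waits), "\n")
  invisible(x)
}

#' Filter pooled waits from a run
#'
#' @param run an `ecr_run`.
#' @param resource,patient_class optional filters; `resource` may contain
#'   several names (e.g. both biplane suites).
#' @return data.table of waits.
#' @export
run_waits <- function(run, resource = NULL, patient_class = NULL) {
  stopifnot(inherits(run, "ecr_run"))
  w <- run$waits
  if (!is.null(resource)) {
    keep <- w$resource %in% resource
    w <- w[keep, ]
  }
  if (!is.null(patient_class)) {
    keep <- w$patient_class %in% patient_class
    w <- w[keep, ]
  }
  w
}

#' ECR-patient waits for the biplane suite(s)
#'
#' Convenience filter: stroke-class waits at any `angio_inr*` suite — the
#' headline quantity of the scenario experiments.
#'
#' @param run an `ecr_run`.
#' @export
ecr_suite_waits <- function(run) {
  w <- run$waits
  w[w$patient_class == "stroke" & grepl("^angio_inr", w$resource), ]
}

#' Summarize a run
#'
#' @param run an `ecr_run`.
#' @return list (JSON-serializable): scenario, replications, horizon_days,
#'   per-resource median utilization, per-class and per-class-by-resource
#'   wait statistics (n, mean, sd, zero-wait fraction).
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "ecr_run"))
  u <- run$utilization
  med_util <- tapply(u$utilization, u$resource, stats::median)
  w <- run$waits
  cls_stats <- function(d) list(
    n = nrow(d), mean_wait = mean(d$wait_min), sd = stats::sd(d$wait_min),
    zero_wait_fraction = mean(d$wait_min <= 1e-9))
  per_class <- lapply(split(w, w$patient_class), cls_stats)
  per_class_resource <- lapply(split(w, paste(w$patient_class, w$resource,
                                              sep = "@")), cls_stats)
  list(scenario = run$meta$scenario,
       replications = run$meta$replications,
       horizon_days = run$meta$horizon_days,
       seed = run$meta$seed,
       median_utilization = as.list(med_util),
       per_class = per_class,
       per_class_resource = per_class_resource)
}

#' Compare two runs
#'
#' Per resource-and-class pooled mean wait deltas (positive = `run_b`, the
#' comparator/baseline, waited longer, i.e. `run_a` improves), per-resource
#' median utilization deltas, and the disability-free-life conversion of the
#' ECR-at-biplane-suite delta.
#'
#' @param run_a scenario run (`ecr_run`).
#' @param run_b baseline run (`ecr_run`).
#' @return list with `wait_deltas` (data.frame), `utilization_deltas`,
#'   `ecr_delta_min`, `dfl`.
#' @export
compare_runs <- function(run_a, run_b) {
  stopifnot(inherits(run_a, "ecr_run"), inherits(run_b, "ecr_run"))
  if (run_a$meta$horizon_days != run_b$meta$horizon_days ||
      run_a$meta$replications != run_b$meta$replications)
    stop("compare_runs: runs differ in horizon or replication count")
  wa <- run_a$waits; wb <- run_b$waits
  keys <- unique(rbind(unique(wa[, c("patient_class", "resource")]),
                       unique(wb[, c("patient_class", "resource")])))
  deltas <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    cl <- keys$patient_class[i]; rs <- keys$resource[i]
    a <- wa$wait_min[wa$patient_class == cl & wa$resource == rs]
    b <- wb$wait_min[wb$patient_class == cl & wb$resource == rs]
    data.frame(patient_class = cl, resource = rs,
               n_a = length(a), n_b = length(b),
               mean_a = if (length(a)) mean(a) else NA_real_,
               mean_b = if (length(b)) mean(b) else NA_real_,
               delta_min = (if (length(b)) mean(b) else NA_real_) -
                 (if (length(a)) mean(a) else NA_real_))
  }))
  ua <- run_a$utilization; ub <- run_b$utilization
  ru <- union(unique(ua$resource), unique(ub$resource))
  util_deltas <- data.frame(
    resource = ru,
    median_a = vapply(ru, function(r) {
      x <- ua$utilization[ua$resource == r]
      if (length(x)) stats::median(x) else NA_real_ }, 0),
    median_b = vapply(ru, function(r) {
      x <- ub$utilization[ub$resource == r]
      if (length(x)) stats::median(x) else NA_real_ }, 0))
  util_deltas$delta <- util_deltas$median_b - util_deltas$median_a
  ea <- ecr_suite_waits(run_a); eb <- ecr_suite_waits(run_b)
  ecr_delta <- if (nrow(ea) && nrow(eb)) mean(eb$wait_min) - mean(ea$wait_min)
               else NA_real_
  list(wait_deltas = deltas, utilization_deltas = util_deltas,
       ecr_delta_min = ecr_delta,
       dfl = if (is.na(ecr_delta)) NULL else disability_free_life(ecr_delta))
}

# --- run persistence -------------------------------------------------------

#' Save / load a replication run as plain text
#'
#' `save_run` writes `waits.csv`, `utilization.csv`, `counts.csv`,
#' `summary.json` and `meta.json` into a directory; `load_run` reconstructs
#' an `ecr_run` (without the full parameter object) sufficient for
#' [compare_runs()].
#'
#' @param run an `ecr_run`.
#' @param dir directory (created if missing).
#' @return `save_run` the directory, `load_run` an `ecr_run`.
#' @export
save_run <- function(run, dir) {
  stopifnot(inherits(run, "ecr_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(run$waits, file.path(dir, "waits.csv"))
  data.table::fwrite(run$utilization, file.path(dir, "utilization.csv"))
  data.table::fwrite(run$counts, file.path(dir, "counts.csv"))
  meta <- run$meta[c("scenario", "horizon_days", "replications", "seed",
                     "warmup_days")]
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(summarize_run(run), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_run
#' @export
load_run <- function(dir) {
  need <- file.path(dir, c("waits.csv", "utilization.csv", "meta.json"))
  if (!all(file.exists(need)))
    stop("load_run: '", dir, "' is not a saved run (missing ",
         paste(basename(need)[!file.exists(need)], collapse = ", "), ")")
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  cfile <- file.path(dir, "counts.csv")
  structure(list(
    waits = data.table::fread(file.path(dir, "waits.csv")),
    utilization = data.table::fread(file.path(dir, "utilization.csv")),
    counts = if (file.exists(cfile)) data.table::fread(cfile) else NULL,
    meta = meta), class = "ecr_run")
}

# --- configuration files ---------------------------------------------------

parse_clock <- function(x, path, errs) {
  if (is.numeric(x)) return(list(val = x, errs = errs))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) == 0)
    return(list(val = NA_real_,
                errs = c(errs, paste0(path, ": cannot parse time '", x, "'"))))
  list(val = as.numeric(m[2]) * 60 + as.numeric(m[3]), errs = errs)
}

#' Load a model/run configuration file
#'
#' Reads YAML or JSON (by extension) with optional sections `patients`
#' (annual counts, or `{interarrival_min: X}` per stream), `resources`
#' (`day_capacity`, `night_capacity`, `day_start`, `day_end`,
#' `eligible_classes`), `durations` (`distribution`, `mean`, `cv` per step),
#' `branching` (probability overrides) and `run` (`horizon_days`,
#' `replications`, `seed`, `warmup_days`, `scenario`, `ed_background`,
#' `demand_multiplier`). Unspecified keys take the shipped defaults. Every
#' violated invariant is reported with its key path; unknown keys warn.
#'
#' @param path config file.
#' @return list with `params` ([ecr_params()]) and `run` (a list of run
#'   settings).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  errs <- character(0)
  known_sections <- c("patients", "resources", "durations", "branching", "run")
  unknown <- setdiff(names(cfg), known_sections)
  if (length(unknown))
    warning("load_config: ignoring unknown section(s): ",
            paste(unknown, collapse = ", "))

  counts <- default_annual_counts()
  ia_over <- list()
  for (nm in names(cfg$patients)) {
    v <- cfg$patients[[nm]]
    kp <- paste0("patients.", nm)
    if (!nm %in% names(counts)) {
      warning("load_config: unknown patient stream '", nm, "'"); next
    }
    if (is.list(v)) {
      if (!is.null(v$interarrival_min)) {
        if (v$interarrival_min <= 0)
          errs <- c(errs, paste0(kp, ".interarrival_min: must be > 0"))
        else ia_over[[nm]] <- v$interarrival_min
      }
      if (!is.null(v$annual_count)) counts[[nm]] <- v$annual_count
    } else {
      counts[[nm]] <- v
    }
    if (counts[[nm]] < 0) errs <- c(errs, paste0(kp, ": negative annual count"))
  }

  res <- default_resources()
  for (nm in names(cfg$resources)) {
    v <- cfg$resources[[nm]]
    kp <- paste0("resources.", nm)
    dc <- v$day_capacity %||% NULL
    nc <- v$night_capacity %||% dc
    if (is.null(dc)) { errs <- c(errs, paste0(kp, ".day_capacity: required")); next }
    if (dc < 0 || nc < 0) {
      errs <- c(errs, paste0(kp, ": negative capacity")); next
    }
    ds <- parse_clock(v$day_start %||% "08:00", paste0(kp, ".day_start"), errs)
    errs <- ds$errs
    de <- parse_clock(v$day_end %||% "17:00", paste0(kp, ".day_end"), errs)
    errs <- de$errs
    if (is.na(ds$val) || is.na(de$val)) next
    sched <- if (dc == nc) constant_schedule(dc) else
      shift_schedule(dc, nc, ds$val, de$val)
    old <- res[[nm]]
    res[[nm]] <- resource_spec(
      nm, sched,
      v$eligible_classes %||% (if (!is.null(old)) old$eligible_classes
                               else ECR_CLASSES),
      suite = if (!is.null(old)) old$suite else isTRUE(v$suite),
      human = if (!is.null(old)) old$human else isTRUE(v$human))
  }

  durs <- default_durations()
  for (nm in names(cfg$durations)) {
    v <- cfg$durations[[nm]]
    kp <- paste0("durations.", nm)
    d <- tryCatch(duration_spec(v$distribution %||% "lognormal",
                                mean = v$mean, cv = v$cv %||% 0.5),
                  error = function(e) {
                    errs <<- c(errs, paste0(kp, ": ", conditionMessage(e)))
                    NULL
                  })
    if (!is.null(d)) durs[[nm]] <- d
  }

  branching <- NULL
  if (!is.null(cfg$branching)) {
    branching <- unlist(cfg$branching)
    bad <- branching < 0 | branching > 1
    if (any(bad))
      errs <- c(errs, paste0("branching.", names(branching)[bad],
                             ": probability outside [0,1]"))
  }

  runc <- cfg$run %||% list()
  run <- list(
    horizon_days = runc$horizon_days %||% 365,
    replications = runc$replications %||% 30,
    seed = runc$seed %||% 1L,
    warmup_days = runc$warmup_days %||% 0,
    scenario = runc$scenario %||% "baseline")
  if (run$replications < 1) errs <- c(errs, "run.replications: must be >= 1")
  if (run$horizon_days <= run$warmup_days || run$warmup_days < 0)
    errs <- c(errs, "run: need horizon_days > warmup_days >= 0")

  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))

  params <- ecr_params(
    annual_counts = counts,
    interarrival_min = if (length(ia_over)) ia_over else NULL,
    durations = durs,
    branch_probs = branching,
    resources = res,
    demand_multiplier = runc$demand_multiplier %||% 1,
    ed_background = runc$ed_background %||% TRUE)
  list(params = params, run = run)
}

#' Write a configuration file equivalent to a parameter set
#'
#' @param params an [ecr_params()].
#' @param run optional run-settings list as returned by [load_config()].
#' @param path output path (`.yaml` or `.json`).
#' @export
save_config <- function(params, path, run = NULL) {
  stopifnot(inherits(params, "ecr_params"))
  cfg <- list(
    patients = as.list(params$annual_counts),
    durations = lapply(params$durations, function(d)
      list(distribution = d$distribution, mean = d$mean, cv = d$cv)),
    branching = as.list(params$branch_probs))
  if (!is.null(run)) cfg$run <- run
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
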