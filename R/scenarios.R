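# Named, pure transformations of the baseline parameters reproducing the
# capacity-planning experiments: exclusive use of the biplane suite, a second
# biplane suite, extended working hours, and demand growth.

#' Scenario transformations
#'
#' Each transformation takes an [ecr_params()] and returns a modified copy;
#' the input is never mutated, and applying a transform twice is idempotent
#' (except demand scaling, which composes multiplicatively).
#'
#' * `apply_exclusive_use`: elective IR patients lose access to the biplane
#'   suite (`angio_inr`), which remains available to stroke, elective INR and
#'   emergency IR patients.
#' * `apply_two_angioinr`: the single-plane suite is replaced by a second
#'   biplane suite (`angio_inr2`); all four interventional classes route
#'   between the two by shortest queue. Staffing is unchanged.
#' * `apply_extended_schedule`: every human resource's day shift is stretched
#'   by `extra_hours` (1 or 2) past 17:00, and the elective service-start
#'   window stretches with it. Physical machines are untouched.
#' * `apply_demand_multiplier`: arrival rates are multiplied by `k`; by
#'   default only the stroke/ECR funnel grows (the reported demand growth is
#'   ECR-specific), `scope = "all"` scales every stream.
#'
#' @param params an [ecr_params()].
#' @param extra_hours 1 or 2.
#' @param k positive demand multiplier.
#' @param scope `"funnel"` or `"all"`.
#' @return a modified `ecr_params`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
apply_exclusive_use <- function(params) {
  stopifnot(inherits(params, "ecr_params"))
  r <- params$resources
  if (!"angio_inr" %in% names(r))
    stop("apply_exclusive_use: model has no angio_inr resource")
  r$angio_inr$eligible_classes <-
    setdiff(r$angio_inr$eligible_classes, "elective_ir")
  params$resources <- r
  params
}

#' @rdname scenarios
#' @export
apply_two_angioinr <- function(params) {
  stopifnot(inherits(params, "ecr_params"))
  r <- params$resources
  if (!"angio_inr" %in% names(r))
    stop("apply_two_angioinr: model has no angio_inr resource")
  all4 <- c("stroke", "elective_inr", "emergency_ir", "elective_ir")
  r$angio_ir <- NULL
  r$angio_inr$eligible_classes <- all4
  if (!"angio_inr2" %in% names(r)) {
    r2 <- r$angio_inr
    r2$name <- "angio_inr2"
    # keep the two suites adjacent in declaration order (tie-break order)
    i <- match("angio_inr", names(r))
    r <- append(r, stats::setNames(list(r2), "angio_inr2"), after = i)
  } else {
    r$angio_inr2$eligible_classes <- all4
  }
  params$resources <- r
  params
}

#' @rdname scenarios
#' @export
apply_extended_schedule <- function(params, extra_hours) {
  stopifnot(inherits(params, "ecr_params"))
  if (!extra_hours %in% c(1, 2))
    stop("apply_extended_schedule: extra_hours must be 1 or 2")
  base_end <- params$day_end
  new_end <- base_end + 60 * extra_hours
  params$resources <- lapply(params$resources, function(r) {
    if (r$human && length(r$schedule$caps) > 1) {
      day_cap <- max(r$schedule$caps)
      night_cap <- min(r$schedule$caps)
      r$schedule <- shift_schedule(day_cap, night_cap, params$day_start, new_end)
    }
    r
  })
  params$extra_hours <- extra_hours
  params
}

#' @rdname scenarios
#' @export
apply_demand_multiplier <- function(params, k, scope = params$demand_scope) {
  stopifnot(inherits(params, "ecr_params"))
  if (k <= 0) stop("apply_demand_multiplier: k must be > 0")
  params$demand_multiplier <- params$demand_multiplier * k
  params$demand_scope <- scope
  params
}

#' Parse and apply a scenario specification
#'
#' `spec` is a comma-separated list applied left to right, each element one
#' of `baseline`, `exclusive`, `two-inr`, `extended:H` (H = 1 or 2) or
#' `demand:K` (K > 0). Underscore aliases (`exclusive_use`, `two_angioinr`,
#' `extended_schedule:H`, `demand_scaled:K`) are accepted.
#'
#' @param params baseline [ecr_params()].
#' @param spec scenario string, e.g. `"exclusive,extended:1"`.
#' @return transformed `ecr_params`.
#' @export
apply_scenario <- function(params, spec) {
  stopifnot(inherits(params, "ecr_params"))
  for (part in strsplit(spec, ",", fixed = TRUE)[[1]]) {
    part <- trimws(part)
    if (part == "" || part == "baseline") next
    kv <- strsplit(part, ":", fixed = TRUE)[[1]]
    key <- kv[1]
    arg <- if (length(kv) > 1) as.numeric(kv[2]) else NA_real_
    params <- switch(key,
      exclusive = , exclusive_use = apply_exclusive_use(params),
      "two-inr" = , two_angioinr = apply_two_angioinr(params),
      extended = , extended_schedule = {
        if (is.na(arg)) stop("scenario 'extended' needs hours, e.g. extended:1")
        apply_extended_schedule(params, arg)
      },
      demand = , demand_scaled = {
        if (is.na(arg)) stop("scenario 'demand' needs a multiplier, e.g. demand:2")
        apply_demand_multiplier(params, arg)
      },
      stop("unknown scenario element '", part, "'"))
  }
  params
}
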