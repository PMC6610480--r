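# Event-calendar executor for a sim_model. Single-threaded, deterministic:
# identical (model, horizon, seed) yields an identical event log.
#
# Grant discipline (non-preemptive): each resource keeps one queue of waiting
# bundle requests ordered by (priority, enqueue sequence). Only the queue head
# may be granted; a head whose bundle is not fully available (or whose
# elective gate is closed) blocks the queue behind it, so no request ever
# overtakes a strictly-higher-priority request for the same resource. A
# bundle request occupies a slot in every member resource's queue and is
# removed from all of them on grant. Capacity drops at shift changes never
# interrupt service: the pool simply admits no new grants until the busy
# count falls below the new capacity.

#' Run a simulation
#'
#' Executes the model's event calendar from time 0 to `horizon` and returns
#' the full event log plus derived per-run tables.
#'
#' Randomness is drawn from named streams (one per arrival source, duration
#' and branch point) derived deterministically from `seed`, so two runs with
#' the same arguments are identical, and paired scenario runs with a shared
#' seed use common random numbers.
#'
#' Event generation stops at `horizon`; entities still queued or in service
#' are flagged `completed = FALSE` in the waits table and are excluded from
#' wait statistics downstream.
#'
#' @param model a [sim_model()].
#' @param horizon run length in minutes (> 0). Default 365 days.
#' @param seed integer root seed for the replication.
#' @param replication,scenario labels copied into the log.
#' @return an object of class `ecr_eventlog`: a list with `records` (the flat
#'   event log: time_min, replication, scenario, entity_id, patient_class,
#'   resource, action, queue_length), `waits` (one row per granted
#'   queue_enter/seize pair and resource), `utilization` (busy-unit-minutes
#'   and capacity-minutes per resource), `counts` (arrivals per source) and
#'   `meta`.
#' @export
sim_run <- function(model, horizon = 365 * 1440, seed = 1L,
                    replication = 1L, scenario = "custom") {
  stopifnot(inherits(model, "sim_model"), horizon > 0)

  res <- model$resources
  nR <- length(res)
  rnames <- names(res)
  rbounds <- lapply(res, function(r) r$schedule$bounds)
  rcaps <- lapply(res, function(r) r$schedule$caps)
  gate <- model$gate_window
  classnames <- unique(vapply(model$sources, function(s) s$patient_class, ""))

  # --- arrivals --------------------------------------------------------
  nS <- length(model$sources)
  src_times <- vector("list", nS)
  src_prio <- vector("list", nS)
  for (i in seq_len(nS)) {
    src <- model$sources[[i]]
    if (!is.null(src$times)) {
      tt <- src$times
      if (is.unsorted(tt)) stop("scripted arrival times of '", src$name,
                                "' must be non-decreasing")
      keep <- tt <= horizon
      src_times[[i]] <- tt[keep]
      if (!is.null(src$priorities)) {
        if (length(src$priorities) != length(src$times))
          stop("priorities of '", src$name, "' must match times")
        src_prio[[i]] <- src$priorities[keep]
      }
    } else if (is.finite(src$interarrival)) {
      rate <- 1 / src$interarrival
      set.seed(derive_seed(seed, paste0("arr_", src$name)))
      n0 <- max(16, ceiling(horizon * rate + 4 * sqrt(horizon * rate) + 10))
      tt <- cumsum(rexp(n0, rate))
      while (tt[length(tt)] < horizon)
        tt <- c(tt, tt[length(tt)] + cumsum(rexp(n0, rate)))
      src_times[[i]] <- tt[tt < horizon]
    } else {
      src_times[[i]] <- numeric(0)
    }
  }
  src_n <- lengths(src_times)
  n_ent <- sum(src_n)

  # --- pre-generated random pools (indexed by entity id) ---------------
  dnames <- names(model$durations)
  dspecs <- model$durations
  dpool <- vector("list", length(dnames))
  if (length(dnames)) for (j in seq_along(dnames)) {
    sp <- dspecs[[j]]
    if (sp$distribution != "scripted" && n_ent > 0) {
      set.seed(derive_seed(seed, paste0("dur_", dnames[j])))
      dpool[[j]] <- switch(sp$distribution,
        fixed = rep.int(as.numeric(sp$mean), n_ent),
        exponential = stats::rexp(n_ent, 1 / sp$mean),
        lognormal = {
          sdl <- sqrt(log(1 + sp$cv^2))
          stats::rlnorm(n_ent, log(sp$mean) - sdl^2 / 2, sdl)
        })
    }
  }
  bnames <- names(model$branch_probs)
  bp <- as.numeric(model$branch_probs)
  bpool <- vector("list", length(bnames))
  if (length(bnames)) for (j in seq_along(bnames)) {
    set.seed(derive_seed(seed, paste0("branch_", bnames[j])))
    bpool[[j]] <- stats::runif(max(n_ent, 1))
  }

  # --- compiled pathways ----------------------------------------------
  # kinds: 1 seize, 2 timeout, 3 release, 4 branch, 5 exit, 6 route_seize
  PW <- vector("list", nS)
  for (i in seq_len(nS)) {
    steps <- model$sources[[i]]$pathway
    PW[[i]] <- lapply(steps, function(st) {
      switch(st$kind,
        seize = list(k = 1L, res = match(st$resources, rnames),
                     units = st$units, gated = isTRUE(st$gated)),
        timeout = list(k = 2L, dur = match(st$duration, dnames)),
        release = list(k = 3L),
        branch = list(k = 4L, br = match(st$prob, bnames)),
        exit = list(k = 5L),
        route_seize = list(k = 6L, cand = match(st$candidates, rnames),
                           extra = match(st$extra, rnames),
                           units = st$units, gated = isTRUE(st$gated)))
    })
  }
  exit_pc <- vapply(PW, length, 0L)

  # --- state -----------------------------------------------------------
  busy <- integer(nR)
  busymin <- numeric(nR)
  QU <- rep(list(integer(0)), nR)
  dirty <- logical(nR)   # resources whose queues need a grant scan

  en_cap <- max(n_ent, 1L)
  en_class <- integer(en_cap); en_prio <- integer(en_cap)
  en_src <- integer(en_cap); en_sidx <- integer(en_cap)
  en_pc <- integer(en_cap); en_hold <- integer(en_cap)
  en_done <- logical(en_cap); en_created <- numeric(en_cap)
  ne <- 0L

  rq_cap <- 256L
  rq_ent <- integer(rq_cap); rq_prio <- integer(rq_cap)
  rq_seq <- numeric(rq_cap); rq_t <- numeric(rq_cap)
  rq_gated <- logical(rq_cap); rq_waiting <- logical(rq_cap)
  rq_res <- vector("list", rq_cap); rq_units <- vector("list", rq_cap)
  nq <- 0L; qseq <- 0

  lg_cap <- 4096L
  lg_t <- numeric(lg_cap); lg_ent <- integer(lg_cap)
  lg_res <- integer(lg_cap); lg_act <- integer(lg_cap); lg_q <- integer(lg_cap)
  lg_n <- 0L

  w_cap <- 1024L
  w_ent <- integer(w_cap); w_res <- integer(w_cap)
  w_t <- numeric(w_cap); w_wait <- numeric(w_cap)
  wn <- 0L

  now <- 0

  log_add <- function(e, r, act, q) {
    n <- lg_n + 1L
    if (n > lg_cap) {
      lg_cap <<- lg_cap * 2L
      length(lg_t) <<- lg_cap; length(lg_ent) <<- lg_cap
      length(lg_res) <<- lg_cap; length(lg_act) <<- lg_cap
      length(lg_q) <<- lg_cap
    }
    lg_t[n] <<- now; lg_ent[n] <<- e; lg_res[n] <<- r
    lg_act[n] <<- act; lg_q[n] <<- q
    lg_n <<- n
  }

  # --- event calendar (binary heap) -----------------------------------
  # Keyed by (time, kind, insertion seq): simultaneous events resolve as
  # arrivals first, then service completions, then schedule rescans, so a
  # patient arriving at the very instant a resource frees competes for it
  # (matching the brute-force oracle's "arrived by t" rule). The kind is
  # folded into the tie-break key as kind * 2^32 + seq.
  hp_cap <- 1024L
  hp_t <- numeric(hp_cap); hp_k <- integer(hp_cap)
  hp_a <- integer(hp_cap); hp_s <- numeric(hp_cap)
  hp_n <- 0L; evseq <- 0
  ev_t <- 0; ev_k <- 0L; ev_a <- 0L

  hpush <- function(t, k, a) {
    n <- hp_n + 1L
    if (n > hp_cap) {
      hp_cap <<- hp_cap * 2L
      length(hp_t) <<- hp_cap; length(hp_k) <<- hp_cap
      length(hp_a) <<- hp_cap; length(hp_s) <<- hp_cap
    }
    evseq <<- evseq + 1
    s <- k * 4294967296 + evseq
    i <- n
    hp_t[i] <<- t; hp_k[i] <<- k; hp_a[i] <<- a; hp_s[i] <<- s
    while (i > 1L) {
      p <- i %/% 2L
      if (hp_t[p] > t || (hp_t[p] == t && hp_s[p] > s)) {
        hp_t[i] <<- hp_t[p]; hp_k[i] <<- hp_k[p]
        hp_a[i] <<- hp_a[p]; hp_s[i] <<- hp_s[p]
        hp_t[p] <<- t; hp_k[p] <<- k; hp_a[p] <<- a; hp_s[p] <<- s
        i <- p
      } else break
    }
    hp_n <<- n
  }

  hpop <- function() {
    ev_t <<- hp_t[1]; ev_k <<- hp_k[1]; ev_a <<- hp_a[1]
    n <- hp_n
    t <- hp_t[n]; k <- hp_k[n]; a <- hp_a[n]; s <- hp_s[n]
    hp_n <<- n - 1L
    n <- n - 1L
    if (n == 0L) return(invisible())
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      if (l > n) break
      c <- l
      if (r <= n && (hp_t[r] < hp_t[l] ||
                     (hp_t[r] == hp_t[l] && hp_s[r] < hp_s[l]))) c <- r
      if (hp_t[c] < t || (hp_t[c] == t && hp_s[c] < s)) {
        hp_t[i] <<- hp_t[c]; hp_k[i] <<- hp_k[c]
        hp_a[i] <<- hp_a[c]; hp_s[i] <<- hp_s[c]
        i <- c
      } else break
    }
    hp_t[i] <<- t; hp_k[i] <<- k; hp_a[i] <<- a; hp_s[i] <<- s
    invisible()
  }

  cap_now <- function(r) rcaps[[r]][findInterval(now %% 1440, rbounds[[r]])]

  grantable <- function(id) {
    if (rq_gated[id]) {
      tod <- now %% 1440
      if (tod < gate[1] || tod >= gate[2]) return(FALSE)
    }
    rs <- rq_res[[id]]; un <- rq_units[[id]]
    for (j in seq_along(rs)) {
      r <- rs[j]
      if (busy[r] + un[j] > rcaps[[r]][findInterval(now %% 1440, rbounds[[r]])])
        return(FALSE)
    }
    TRUE
  }

  scan_set <- function(rs) {
    pending <- as.integer(rs)
    while (length(pending)) {
      r <- pending[1]; pending <- pending[-1]
      repeat {
        q <- QU[[r]]
        if (!length(q)) break
        h <- q[1]
        if (!grantable(h)) break
        rs2 <- rq_res[[h]]; un2 <- rq_units[[h]]
        for (rr in rs2) { qq <- QU[[rr]]; QU[[rr]] <<- qq[qq != h] }
        rq_waiting[h] <<- FALSE
        busy[rs2] <<- busy[rs2] + un2
        busymin[rs2] <<- busymin[rs2] - now * un2
        e <- rq_ent[h]
        for (j in seq_along(rs2)) {
          log_add(e, rs2[j], 3L, length(QU[[rs2[j]]]))
          n <- wn + 1L
          if (n > w_cap) {
            w_cap <<- w_cap * 2L
            length(w_ent) <<- w_cap; length(w_res) <<- w_cap
            length(w_t) <<- w_cap; length(w_wait) <<- w_cap
          }
          w_ent[n] <<- e; w_res[n] <<- rs2[j]
          w_t[n] <<- rq_t[h]; w_wait[n] <<- now - rq_t[h]
          wn <<- n
        }
        en_hold[e] <<- h
        en_pc[e] <<- en_pc[e] + 1L
        advance(e)
        extra <- rs2[rs2 != r]
        if (length(extra)) pending <- unique(c(pending, extra))
      }
    }
  }

  enqueue <- function(e, rs, un, gated) {
    n <- nq + 1L
    if (n > rq_cap) {
      rq_cap <<- rq_cap * 2L
      length(rq_ent) <<- rq_cap; length(rq_prio) <<- rq_cap
      length(rq_seq) <<- rq_cap; length(rq_t) <<- rq_cap
      length(rq_gated) <<- rq_cap; length(rq_waiting) <<- rq_cap
      length(rq_res) <<- rq_cap; length(rq_units) <<- rq_cap
    }
    p <- en_prio[e]
    rq_ent[n] <<- e; rq_prio[n] <<- p
    s <- qseq + 1; qseq <<- s; rq_seq[n] <<- s
    rq_t[n] <<- now; rq_gated[n] <<- gated; rq_waiting[n] <<- TRUE
    rq_res[[n]] <<- rs; rq_units[[n]] <<- un
    nq <<- n
    for (r in rs) {
      q <- QU[[r]]
      pos <- if (length(q)) sum(rq_prio[q] <= p) else 0L
      QU[[r]] <<- append(q, n, after = pos)
      log_add(e, r, 2L, length(q) + 1L)
    }
    dirty[rs] <<- TRUE
  }

  advance <- function(e) {
    repeat {
      st <- PW[[en_src[e]]][[en_pc[e]]]
      k <- st$k
      if (k == 2L) {                         # timeout
        sp_i <- st$dur
        sp <- dspecs[[sp_i]]
        d <- if (sp$distribution == "scripted") {
          i <- en_sidx[e]
          if (i > length(sp$values)) stop("scripted duration pool exhausted")
          sp$values[i]
        } else dpool[[sp_i]][e]
        en_pc[e] <<- en_pc[e] + 1L
        hpush(now + d, 2L, e)
        return(invisible())
      } else if (k == 1L) {                  # seize
        enqueue(e, st$res, st$units, st$gated)
        return(invisible())
      } else if (k == 3L) {                  # release
        h <- en_hold[e]
        if (h == 0L) stop("release without held resources (model bug)")
        rs <- rq_res[[h]]; un <- rq_units[[h]]
        busy[rs] <<- busy[rs] - un
        busymin[rs] <<- busymin[rs] + now * un
        for (j in seq_along(rs)) log_add(e, rs[j], 4L, length(QU[[rs[j]]]))
        en_hold[e] <<- 0L
        en_pc[e] <<- en_pc[e] + 1L
        dirty[rs] <<- TRUE
      } else if (k == 4L) {                  # branch
        u <- bpool[[st$br]][e]
        en_pc[e] <<- if (u < bp[st$br]) en_pc[e] + 1L else exit_pc[en_src[e]]
      } else if (k == 6L) {                  # route by shortest queue
        cand <- st$cand
        best <- cand[1]
        bestocc <- length(QU[[best]]) + busy[best]
        if (length(cand) > 1L) for (j in 2:length(cand)) {
          r <- cand[j]
          occ <- length(QU[[r]]) + busy[r]
          if (occ < bestocc) { best <- r; bestocc <- occ }
        }
        enqueue(e, c(best, st$extra), st$units, st$gated)
        return(invisible())
      } else {                               # exit
        log_add(e, 0L, 5L, 0L)
        en_done[e] <<- TRUE
        return(invisible())
      }
    }
  }

  # --- seed the calendar ----------------------------------------------
  src_ptr <- integer(nS)
  for (i in seq_len(nS)) if (src_n[i] > 0L) {
    src_ptr[i] <- 1L
    hpush(src_times[[i]][1], 1L, i)
  }
  bnds <- sort(unique(c(unlist(rbounds), gate)))
  bnds <- bnds[bnds > 0 & bnds < MINUTES_PER_DAY]
  if (length(bnds)) {
    days <- 0:(ceiling(horizon / MINUTES_PER_DAY) - 1)
    for (tb in as.vector(outer(bnds, days * MINUTES_PER_DAY, "+")))
      if (tb < horizon) hpush(tb, 3L, 0L)
  }

  # --- main loop -------------------------------------------------------
  cls_idx <- match(vapply(model$sources, function(s) s$patient_class, ""),
                   classnames)
  prio_map <- model$priorities
  src_classprio <- vapply(model$sources,
                          function(s) as.integer(prio_map[[s$patient_class]]), 0L)

  # Two-phase processing: drain every event sharing the current timestamp
  # (arrivals first, then completions, then boundary rescans), then run the
  # grant scans. All patients present at an instant therefore compete by
  # priority for capacity freed at that instant, matching the brute-force
  # oracle's "arrived by t" candidate rule.
  handle_event <- function() {
    if (ev_k == 1L) {                        # arrival
      i <- ev_a
      idx <- src_ptr[i]
      if (idx < src_n[i]) {
        src_ptr[i] <<- idx + 1L
        hpush(src_times[[i]][idx + 1L], 1L, i)
      }
      e <- ne + 1L; ne <<- e
      en_class[e] <<- cls_idx[i]
      en_prio[e] <<- if (!is.null(src_prio[[i]]))
        as.integer(src_prio[[i]][idx]) else src_classprio[i]
      en_src[e] <<- i; en_sidx[e] <<- idx
      en_pc[e] <<- 1L; en_hold[e] <<- 0L
      en_created[e] <<- now
      log_add(e, 0L, 1L, 0L)
      advance(e)
    } else if (ev_k == 2L) {                 # timeout end
      advance(ev_a)
    } else {                                 # schedule boundary: rescan
      dirty[] <<- TRUE
    }
  }

  while (hp_n > 0L) {
    hpop()
    if (ev_t > horizon) break
    now <- ev_t
    handle_event()
    while (hp_n > 0L && hp_t[1] == now) {
      hpop()
      handle_event()
    }
    repeat {
      d <- which(dirty)
      if (!length(d)) break
      dirty[d] <- FALSE
      scan_set(d)
    }
  }

  # close the busy-minute integrals of services still running at horizon
  if (ne > 0L) for (e in seq_len(ne)) if (en_hold[e] > 0L) {
    h <- en_hold[e]
    busymin[rq_res[[h]]] <- busymin[rq_res[[h]]] + horizon * rq_units[[h]]
  }

  acts <- c("arrive", "queue_enter", "seize", "release", "exit")
  li <- seq_len(lg_n)
  records <- data.table::data.table(
    time_min = lg_t[li],
    replication = replication,
    scenario = scenario,
    entity_id = lg_ent[li],
    patient_class = classnames[en_class[lg_ent[li]]],
    resource = c("", rnames)[lg_res[li] + 1L],
    action = acts[lg_act[li]],
    queue_length = lg_q[li])

  wi <- seq_len(wn)
  waits <- data.table::data.table(
    replication = replication,
    entity_id = w_ent[wi],
    patient_class = classnames[en_class[w_ent[wi]]],
    resource = rnames[w_res[wi]],
    enqueue_min = w_t[wi],
    wait_min = w_wait[wi],
    completed = en_done[w_ent[wi]])

  capmin <- vapply(res, function(r) capacity_minutes(r$schedule, horizon), 0)
  utilization <- data.table::data.table(
    replication = replication,
    resource = rnames,
    busy_minutes = busymin,
    capacity_minutes = capmin,
    utilization = ifelse(capmin > 0, pmin(busymin / capmin, 1), NA_real_))

  ei <- seq_len(max(ne, 0L))
  counts <- data.table::data.table(
    replication = replication,
    source = names(model$sources)[seq_len(nS)],
    patient_class = classnames[cls_idx],
    arrivals = as.integer(src_n),
    completed = vapply(seq_len(nS), function(i)
      sum(en_done[ei][en_src[ei] == i]), 0L))

  structure(list(records = records, waits = waits, utilization = utilization,
                 counts = counts,
                 meta = list(replication = replication, seed = seed,
                             scenario = scenario, horizon = horizon,
                             gate_window = gate, resources = res)),
            class = "ecr_eventlog")
}

#' @export
print.ecr_eventlog <- function(x, ...) {
  cat("<ecr_eventlog> scenario:", x$meta$scenario,
      " replication:", x$meta$replication,
      " horizon:", x$meta$horizon, "min\n")
  cat("  ", nrow(x$records), "event records,",
      length(unique(x$records$entity_id)) - (0 %in% x$records$entity_id),
      "entities,", nrow(x$waits), "granted seizes\n")
  invisible(x)
}

#' @export
as.data.frame.ecr_eventlog <- function(x, ...) as.data.frame(x$records)

#' Write an event log to CSV
#'
#' Canonical flat schema: `time_min, replication, scenario, entity_id,
#' patient_class, resource, action, queue_length`, UTF-8 with a header row.
#'
#' @param log an `ecr_eventlog`.
#' @param path output file path.
#' @export
write_eventlog_csv <- function(log, path) {
  stopifnot(inherits(log, "ecr_eventlog"))
  data.table::fwrite(log$records, path)
  invisible(path)
}
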