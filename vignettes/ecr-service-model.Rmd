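---
title: "Modelling an endovascular clot retrieval service with ecrdes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an endovascular clot retrieval service with ecrdes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrdes)
```

`ecrdes` simulates a comprehensive stroke service delivering endovascular
clot retrieval (ECR) as a discrete event system: patients are entities,
angiography suites, scanners and staff groups are finite resource pools, and
the simulation clock jumps between instantaneous events (arrivals, resource
seizures, releases). This vignette is the package's account of its own
science: the model and its assumptions, the parameters that matter, the
numerical choices, and what the validation suite does and does not
establish.

## The service being modelled

The modelled institution runs one biplane angiography suite (`angio_inr`,
capable of neuro- and body-interventional work), one single-plane suite
(`angio_ir`, body work only), two CT scanners, one interventional
neuroradiologist (INR, on call 24 h), interventional radiologists (IR, 2 by
day and 1 overnight), angiography nurses/technologists (6 day / 3 night), an
ED team of 10 and a stroke team of 1. Day shift is 08:00–17:00.

Four pathways compete for these pools:

1. **Stroke**: ED triage → stroke-team assessment → CT scan → two
   eligibility branches (acute ischemic stroke; ECR candidacy) → ECR
   procedure seizing *simultaneously* one biplane suite, the INR and one
   staff member.
2. **Elective INR** (cerebral angiograms etc.): staff preparation, then the
   procedure seizing {biplane suite, INR, staff}.
3. **Emergency IR** and 4. **elective IR**: staff preparation, then the
   procedure seizing {suite, IR, staff}, where the suite is chosen between
   `angio_inr` and `angio_ir` by shortest queue.

Annual volumes (logged 2016–17) parameterize everything: ED 107,700;
suspected stroke 750; AIS 450; ECR 58; elective INR 104; emergency IR 468;
elective IR 3,805. A stream seen $N$ times a year has Poisson arrivals with
mean gap $525{,}600/N$ minutes; the stroke funnel thins with probabilities
$750/107{,}700$, $450/750$ and $58/450$, so the downstream rows emerge in
expectation rather than being sampled independently.

## Queueing discipline

* **Non-preemptive priorities.** Stroke requests (priority 0) enter any
  queue ahead of emergency IR (1), which enters ahead of electives (2);
  equal priorities are FIFO. A service in progress is never interrupted —
  an arriving stroke patient overtakes the queue but still waits for the
  suite to be vacated.
* **Atomic bundle seizure.** A procedure needs suite + physician + staff
  *at once*. The requesting patient waits holding nothing until every
  member has a free unit, which eliminates hold-and-wait deadlock by
  construction. While waiting, the request occupies a slot in every member
  pool's queue (this is visible to the shortest-queue rule).
* **Head-only grants.** Each pool grants strictly from the head of its
  queue; a head whose bundle is incomplete blocks those behind it. This is
  the simplest discipline under which no request is ever granted while a
  strictly-higher-priority request for the same pool waits.
* **Shortest-queue routing** counts *waiting requests plus busy units*.
  Counting waiting requests alone, with the deterministic first-declared
  tie-break, would send every arrival to the first suite whenever no queue
  has formed — an idle `angio_ir` would never be chosen while `angio_inr`
  is busy-but-queueless, which contradicts both common sense and the
  service's observed behaviour (elective IR work occupies the biplane suite
  roughly half the time). Occupancy counting is also what the established
  R simulation framework for such models does. Ties go to declaration
  order, for reproducibility.
* **Shift changes.** Capacity is a daily-repeating step function. When a
  shift change drops capacity below the busy count, running services finish
  normally; the pool admits no new grants until the busy count falls below
  the new capacity. Capacity increases trigger an immediate queue rescan.
* **Elective gating.** Elective procedures may queue at any hour but may
  only *start* between 08:00 and 17:00 (the window stretches with the
  extended-hours scenario). Arrival rates are not gated: the annual counts
  were logged over full years.

**Same-instant semantics.** Events are processed in two phases per
timestamp: first all arrivals, then all service completions and schedule
changes, and only then are grants decided. Every patient present at an
instant therefore competes by priority for capacity freed at that instant.
Remaining ties resolve by insertion order. This convention is what makes
the kernel agree *exactly* with the brute-force oracle on integer-time
instances.

## Service durations (calibration, not ground truth)

The source service's procedure durations were never published. The shipped
defaults are lognormal with coefficient of variation 0.5 and means: ED
triage 15 min, stroke assessment 20, CT scan 20, angiography preparation
30, ECR procedure 120, elective INR procedure 120, emergency IR 60,
elective IR 60. They were chosen once so that baseline biplane-suite
utilization lands near the reported ~26% (the shipped world measures
~30%), and are not revisited. Absolute wait times from this model should
therefore not be read literally; *differences between scenarios under
common random numbers* are the meaningful output. All durations are
configurable (`durations` section of the config file).

## Randomness and replications

Each replication gets a root seed (`xor(seed, replication)`); every arrival
stream, duration sampler and branch point draws from its own named stream
derived deterministically from the root seed. Two consequences: identical
inputs give byte-identical event logs, and paired scenario runs with the
same seed share their random streams (common random numbers), so scenario
deltas are far less noisy than independent runs. Branch outcomes and
durations are indexed by entity, so the same patient makes the same
draws across scenarios wherever pathways coincide. The default experiment
is 30 replications of 365 days.

The ~106,950 annual ED presentations that are not suspected strokes touch
only the 10-strong ED team (offered load ≈ 0.31), never the angiography
pathways. By Poisson thinning/superposition, simulating them as a separate
background stream — or not at all — leaves the stroke stream's law
unchanged. `ed_background = FALSE` drops them for a ~20× speedup; the test
suite and acceptance script use this setting.

## Outcome measures

* **Wait time**: queue-entry to grant, per patient and resource. Patients
  still queued or in service at the horizon are excluded from wait
  statistics (avoiding censoring bias); the fixed warm-up truncation
  (default 0 days) applies to wait samples only.
* **Standardized wait density**: the histogram density (default bin 1 min)
  of strictly positive waits divided by the number of zero-wait patients
  (zero meaning ≤ 1e-9 min, absorbing same-instant grants). Most patients
  do not wait, so this ratio is comparable across scenarios and demand
  levels. It is undefined when nobody waited zero — the package then asks
  for raw densities instead.
* **Utilization**: busy-unit-minutes over scheduled capacity-minutes;
  reported as the median across replications. Services still running at the
  horizon are clipped there. The engine integrates this exactly during the
  run, and an independent record-based computation in the metrics module is
  tested against it.
* **Disability-free life**: wait reductions convert at 4.2 days per minute;
  the reporting view rounds weeks to the nearest half.

## Scenarios

Pure parameter transformations, composable left to right
(`"exclusive,extended:1"`):

* `exclusive` — elective IR patients lose biplane-suite access;
* `two-inr` — the single-plane suite is replaced by a second biplane suite,
  all four classes route between the two, staffing unchanged;
* `extended:H` — every *human* pool's day shift, and the elective start
  window, stretch by H ∈ {1, 2} hours (machines have no schedule);
* `demand:K` — arrival rates scale by K; by default only the stroke/ECR
  funnel (the observed growth is ECR-specific), optionally all streams.

With the shipped world and common random numbers, exclusive use shortens
mean ECR waits by ~8 min (the suite's utilization drops from ~30% to ~9%),
the second biplane suite by ~3 min, and demand doubling/tripling lengthens
waits while the biplane suite remains the dominant ECR bottleneck.

**A non-result, on purpose.** Extending staffed hours changes ECR waits by
less than a minute here under *both* baseline and exclusive use, with
paired differences well inside Monte-Carlo noise at 30 replications
(|t| ≈ 1). Mechanically this is because the ECR bundle's members are
barely schedule-sensitive: the suite is a machine, the INR works 24 h, and
three staff overnight rarely bind. Which arm benefits "more" from an extra
hour is therefore not resolved in this model world — a conclusion that
depends on the unpublished true durations. The corresponding acceptance
expectation is left failing rather than widened, and the analysis lives
here and in the repository's decision notes.

## Validation: what a green test establishes

The kernel is checked three ways: simulated M/M/1 and M/M/2 mean queue
waits against the closed forms $W_q = \lambda/(\mu(\mu-\lambda))$ and
Erlang C at traffic intensities 0.3–0.9 (within three batch-means standard
errors); *exact* per-entity agreement with a brute-force chronological
single-server simulator on randomized integer-time priority instances; and
conservation/determinism properties on the full service model (seize/release
pairing, capacity never exceeded at grant instants, identical seeds give
identical logs, arrival counts recover the annual volumes).

These establish that the queueing mechanics are right. They do not
establish that the service's *durations* are right (unpublished, see
above), nor that real arrivals are homogeneous Poisson — seasonality,
time-of-day and day-of-week structure, inter-hospital transfers and
clinical heterogeneity are all outside this model.

## Numerical choices

Time is real-valued minutes throughout (a year is 525,600 min). The event
calendar is a binary heap keyed by (time, event-kind, insertion order).
Zero-wait tolerance is 1e-9 min. All tie-breaks — equal priorities, equal
queue lengths, simultaneous events — are deterministic (FIFO, declaration
order, insertion order), so every number the package prints is regenerable
from its seed.
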