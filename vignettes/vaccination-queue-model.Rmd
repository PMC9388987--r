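---
title: "Modelling vaccination clinics as stochastic queue networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vaccination clinics as stochastic queue networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxflow)
```

## The model

vaxflow simulates one clinic day of a COVID-19 vaccination site as a
stochastic queue network. Two layouts are built in:

* **Mass vaccination hub** — patients traverse Entrance, Registration,
  Assessment, Vaccination and Observation in order, with a short walking
  lag between consecutive stations.
* **GP clinic** — a smaller site where the same tasks are folded into
  three stations: Registration, Vaccination and Observation, with
  negligible walking time.

Each staffed station is a multi-server queue with first-come-first-served
(FCFS) discipline: patients are served by the next available staff member
in order of arrival at that station. The post-vaccination observation area
is also modelled as a queue, but its "servers" are seats — a patient can
only enter observation when a seat is free. Staff who supervise the
observation area do not serve queueing patients and are not counted as
staff.

Vaccine doses must be drawn up shortly before administration, so dose
preparation is modelled as a parallel queue rather than an attribute of
the vaccination station. One dose is demanded per booking and released
into the preparation queue at the start of the booking's appointment slot;
preparation staff process dose requests FCFS. The prepared-dose stream
joins the patient stream at the vaccination station as a fork/join: the
i-th patient to reach vaccination consumes the i-th completed dose and can
start service only when both are ready. Doses prepared for patients who
never show up are counted as wastage (preparation staff cannot foresee
no-shows); they have no further queue effect because later patients simply
consume the next dose in line.

### The queue-assignment computation

The engine (`queue_step()`) avoids an event calendar. Customers are taken
in arrival order; each is assigned to the server that becomes free
earliest, with

\[
\text{start}_i = \max(\text{arrival}_i,\; \min_s \text{free}_s), \qquad
\text{depart}_i = \text{start}_i + \text{service}_i ,
\]

after which the chosen server's free time becomes the customer's
departure. For FCFS queues with per-customer service draws this is
equivalent to a discrete-event simulation — the test suite checks
exact equality of all start and departure times against an independently
implemented event-driven simulator on a thousand random instances, and
long-run mean waits against the Erlang-C closed form for M/M/1 and M/M/2
systems. Ties between equally free servers go to the lowest server index;
departure times are invariant to this choice, it merely fixes
server-occupancy traces for reproducibility.

Stations are chained by feeding one station's departures (plus any walking
lag) to the next as arrivals. Because service times and lags are random,
patients can overtake one another between stations; patients are therefore
re-ranked by ready time before each station, so FCFS always applies to
station-arrival order, not to the original booking order.

## Inputs and their defaults

### Service times

Service times are *shifted* parametric distributions: a fixed minimum plus
a non-negative random part, `value = shift + base`. The published
parameterisation uses shifted exponentials — most patients are quick, a
minority slow — with observation times bimodal:

| Station (hub) | Distribution | Median (min) |
|---|---|---|
| Preparation | 1 + exp(rate 3) | 1.23 |
| Entrance | 2 + exp(rate 1) | 2.69 |
| Registration | 3 + exp(rate 0.7) | 3.99 |
| Assessment | 2 + exp(rate 1) | 2.69 |
| Vaccination | 3 + exp(rate 1) | 3.69 |
| Observation | Normal(20, 0.5) / adverse 20 + exp(rate 0.1) | 20.0 |

GP clinics use preparation 1 + exp(3), registration 3 + exp(1),
vaccination 5 + exp(0.5) and the same observation mixture. The
exponential `rate` is a true rate: the registration median is
\(3 + \ln 2 / 0.7 \approx 4.0\) minutes. Five families are supported for
user-specified services (exponential, normal, lognormal, gamma, Weibull),
plus `uniform` and `deterministic` for lags and degenerate cases.

Two numerical conventions matter here. First, families whose base draw can
be negative (normal, uniform) are rejection-sampled until the draw is at
least the shift, so service times are always non-negative; with the
default Normal(20, 0.5) observation times the rejection branch is never
triggered in practice (a negative draw is a 40-sigma event). Second,
`quantile()` returns the quantile of the *truncated* base distribution for
those families, so analytic quantiles and sampled draws always describe
the same distribution.

The observation mixture draws each patient's adverse flag as an
independent Bernoulli (default probability 0.02) and then the duration
from the component matching the flag — the simplest construction
consistent with a small random subset of patients reacting adversely, and
the one that lets downstream analyses condition on the flag. Both
networks use sigma = 0.5 for the non-adverse component.

### Appointments and arrivals

Clinics run a fixed appointment system over eight hours (clock 0 =
opening, times in decimal minutes throughout). Hubs issue appointments on
the hour (8 slots; 60/120/180 bookings per slot at low/medium/high
capacity); GP clinics issue them every ten minutes (48 slots; 2/4/6 per
slot). These booking levels were calibrated — see below — so that the
baseline models keep the pooled median processing time under 60 minutes
and all staff utilisations under 0.8.

Patients do not arrive exactly on time. The arrival offset defaults to
Normal(-10, 5) minutes: the median patient is ten minutes early and about
2.3% arrive at or after their slot time, matching the qualitative
assumption that most people arrive somewhat before their allotted time
while a smaller proportion arrive on or after. The distribution is fully
user-overridable, since only that qualitative behaviour — not a
distribution — is given. Patients whose offset would place them before
opening are clamped to the opening time, so the first slot produces a
queue at the door when the clinic opens, as real mass-vaccination sites
do. Each booking independently no-shows with probability 0.02.

### Staffing

Published staffing tables keep the ratio of staff across stations fixed
while scaling total capacity, e.g. three registration staff per
preparation staff member at any hub size:

* Hub (preparation, entrance, registration, assessment, vaccination):
  (2,4,6,4,5), (4,8,12,8,10), (6,12,18,12,15); 25/50/75 observation
  seats; 21/42/63 total staff.
* GP (preparation, registration, vaccination): (1,1,2), (2,2,4), (3,3,6);
  5/10/15 seats; 4/8/12 total staff.

The staff-shortage sweep removes staff one at a time. Within each removal
cycle stations are ranked by current server count, largest first, ties
toward the more downstream station, and each loses one server in that
order (stations already at one server are skipped; no station may reach
zero). The published analysis does not say which stations lose staff, so
this rule — which erodes the proportional shape as slowly as possible —
is this package's choice; explicit per-station staffing vectors can be
supplied to test alternatives.

### Walking lags and dose release

Two quantities the study design leaves unquantified are fixed here once:

* **Walking time** between hub stations: Uniform(0.5, 2) minutes per
  transition (four transitions), a plausible range for a large venue;
  configurable, and absent at GP clinics.
* **Dose release**: dose requests enter the preparation queue at their
  slot's start time. Releasing a slot's doses when the slot opens mirrors
  the practice of drawing up doses just ahead of the patients booked for
  that period. With the published staffing the preparation queue is
  rarely the binding constraint, consistent with the study's results.

## Queue performance metrics

* **Processing time** — per patient, departure from observation minus
  arrival at the first station, in minutes (walking lags included).
* **Staff utilisation** — per station, delivered service minutes divided
  by `n_servers x horizon`, where the horizon is the span of the
  simulation run: first arrival into the system to last departure out of
  it, shared by all stations. The source description ("the average
  proportion of staff that are serving a patient across the simulation
  run") fixes the numerator but not the horizon; measuring each station
  over its own busy span was considered and rejected, because upstream
  stations finish their work well before the day ends, which shrinks
  their denominator and inflates utilisation above what the published
  booking levels were calibrated to keep under 0.8.
* **Throughput** — patients completing the network per clinic day. All
  booked attendees are processed to completion even past the eight-hour
  mark (overtime), so throughput equals attendance and the processing
  times of late patients include any end-of-day spillover.
* **Dose wastage** — doses prepared minus patients vaccinated.

Each scenario runs 20 independent replications of the clinic day
(the replication count used in the study; adequate for stable estimates
of both queue metrics at these sample sizes). Pooling concatenates
patient-level processing times across replications before taking
percentiles; per-replication spread is reported alongside. Replications
share an identical design, so concatenation agrees with averaging
quantiles up to Monte-Carlo noise. Sample percentiles use the
median-unbiased convention (R's type 8), fixed here because no convention
is stated in the source material.

Seeding: a scenario's base seed initialises R's RNG once and one sub-seed
per replication is drawn from it (`derive_seeds()`); the manifest written
with every run records all of them, so any single replication — or the
entire run — can be reproduced exactly.

## Scenarios and calibration

```{r, eval = FALSE}
cfg <- scenario_config("hub", "medium", reps = 20, seed = 1)
run <- run_baseline(cfg)
glance(run)

whatif_arrivals(cfg, n_steps = 5) # +10 arrivals/hour per step (hub)
whatif_staff(cfg, max_reduction = 5) # largest-station-first removals

calibrate_appointments("gp", "medium", median_max = 60, util_max = 0.8)
```

The arrival sweep increments every slot uniformly (ten extra per hour for
hubs, one extra per ten-minute slot for GP clinics). Sweep points use
independent seeds by default, matching an independent-scenario design;
`common_random_numbers = TRUE` reuses draws across points to sharpen
comparisons.

The calibration search finds the largest integer bookings-per-slot whose
pooled median processing time stays strictly below 60 minutes and whose
maximum station utilisation stays strictly below 0.8 ("remained below"
is read as a strict bound). The search doubles the booking level until
infeasible, then bisects on the integer grid; monotonicity of congestion
in offered load makes the feasible set an interval, up to Monte-Carlo
noise at the boundary. The original calibration procedure is described
only in supplementary material not available here, so the search strategy
is this package's own; only the constraints are taken from the source.

## What the generator does and does not emulate

The synthetic day reproduces the study conditions: appointment-driven
arrivals with early-arrival noise, 2% no-shows, the published service
distributions, staffing and seat counts, 2% adverse reactions, and
overtime completion. It does not model walk-ins, time-varying no-show or
service rates, dose expiry clocks, reneging or balking, staff breaks or
rostering, physical space constraints beyond seat counts, or vaccine
supply logistics. Passing tests therefore demonstrate correctness of the
queueing mechanics and fidelity to the stated assumptions — not that a
real clinic with different arrival behaviour would see these exact
figures. In particular, the arrival-noise distribution is an assumption,
and congested-regime results (the what-if sweeps) are sensitive to how
tightly booked patients cluster around their slot times: more clustered
arrivals produce transient waves and longer waits at the same average
load.

## Degenerate inputs and edge cases

Empty schedules simulate cleanly (header-only outputs); a no-show
probability of one yields an empty day. A dose shortfall at the join
(more attendees than prepared doses) raises an explicit
insufficient-resource error naming the shortfall rather than silently
dropping patients. Staff reductions that would empty a station are
flagged infeasible, and sweep grids carry the flag instead of omitting
the point. Unknown configuration keys are rejected by name.

## Problem sizes

Default scenarios simulate 96–1,440 booked patients per day over 20
replications; the full acceptance recomputation (six baselines plus a
stress scenario, about 68,000 pooled patient records) runs in well under
a minute on one CPU, and the complete test suite — including a
thousand-instance oracle comparison and two 200,000-customer Erlang-C
checks — in under a minute.
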