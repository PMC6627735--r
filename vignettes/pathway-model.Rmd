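---
title: "The transplantation pathway model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The transplantation pathway model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menisim)
library(ggplot2)
```

`menisim` simulates the long-term cost and risk of meniscus transplantation
under two care paradigms. In the **traditional** paradigm a patient who needs
a transplant joins a first-come-first-served queue for a donor allograft and
may deteriorate to total knee arthroplasty (TKA) while waiting. In the
**3D-printing-enabled (3DP)** paradigm a patient-matched implant is printed
on demand, so transplantation happens at arrival and the queue disappears.
Both paradigms share the same post-transplant disease model; they differ in
how patients reach surgery, what the surgery costs, and (in sensitivity
scenarios) how implant quality perturbs the disease model.

## The post-transplant Markov model

After surgery a patient occupies one of four states, checked once a year:

* `NI` — no issue; nothing is done, nothing is charged.
* `R` — meniscal repair, a minor intervention ($2,760 per event).
* `RO` — reoperation for a postoperative condition such as arthrofibrosis
  ($1,770 per event).
* `TKA` — total knee arthroplasty ($14,167), absorbing.

Every patient starts in `NI` immediately after surgery. The annual kernel of
the traditional paradigm is

```{r}
traditional_transition_matrix()
```

`R` and `RO` are the *intermediate* states, and their use is capped: each
transition **into** `R` or `RO` (including an `R` to `RO` escalation) counts
as one intermediate entry, and the transition that would be the third entry
is replaced by `TKA`. The cap models the clinical judgement that a knee
needing repeated re-intervention is headed for arthroplasty. Two readings of
the counting rule are defensible — whether `R` followed directly by `RO` is
one continuing episode or two entries — and the package implements both: the
default counts the escalation as a second entry; `count_reentry = FALSE`
treats consecutive intermediate states as one episode. The choice matters:
the default produces noticeably more forced TKAs over 20 years. We keep the
two-entries reading as the default because the cap is phrased in terms of
*entering* an intermediate state, and an `R` to `RO` move is an entry into a
state the patient was not in.

The capped chain has an exact analytic form: augment the state space with
the number of entries used, `(health state, entries)` for entries `0..cap`,
redirect the `(cap+1)`-th entry to `TKA`, and iterate the augmented kernel.
`tka_probability_by_cycle()` implements this and is the oracle against which
the Monte-Carlo engine is tested (at three binomial standard errors with
50,000 replicates); with `cap = Inf` it collapses to plain matrix powers.

```{r}
tka_probability_by_cycle(traditional_transition_matrix(), 10)[c(1, 2, 6, 11), ]
```

## Implant-quality scenarios

Implant quality enters through a single multiplicative factor on the adverse
transitions: in every non-absorbing row the entries into `R`, `RO` and `TKA`
are multiplied by the factor and the `NI` entry is reset to the complement.
Factors above 1 encode a worse implant, below 1 a better one; a factor that
would push a row's adverse mass past 1 is rejected rather than clipped. The
eight scenarios vary mechanical performance (150% bad / 50% good), shape
fidelity (95% / 90%) and biocompatibility (143% / 111%), and combine all
three multiplicatively into worst (203.775%) and best (49.95%) cases:

```{r}
scenario_factors()
```

We apply the factor to *all* non-absorbing rows, not only the `NI` row. The
scenario definitions speak of scaling "the R, RO and TKA probabilities"
without restricting the row; uniform scaling is the only reading that treats
every adverse transition alike, preserves row-stochasticity through the `NI`
complement, and reduces exactly to the original matrix at factor 1.

## Arrival processes and the allograft queue

The synthetic cohort is the study population itself, not a stand-in for any
registry: patients arrive as a Poisson stream with mean interarrival 1 week,
and 1,040 patients are simulated so arrivals span the 20-year (1,040-week)
window. Donors arrive as a mixed exponential renewal process: for each gap a
mean is drawn uniformly from 1–5 weeks and the gap is exponential with that
mean, giving a marginal mean of 3 weeks. The mixing is resampled per gap by
default; `donor_mixing = "per_stream"` draws one mean per replication
instead, a coarser reading of the same assumption kept as a switch (the two
differ in gap variance, not mean). These processes emulate the *rates* of
the clinical setting but none of its structure — no seasonality, no
donor–patient compatibility, no regional sharing — so passing tests show the
model's internal consistency, not calibration to any waiting-list registry.

The queue is FCFS with infinite capacity: each donor goes to the
longest-waiting patient present at its arrival, a donor arriving to an empty
queue is discarded (allografts are patient-matched at arrival; banking is
not modelled), and a patient who waits 104 weeks (2 years) is removed and
forced into TKA. Ties between a donor arrival and a timeout at the same
instant resolve in favour of the timeout; the event has probability zero
under the continuous arrival distributions, so the rule is a numerical
tie-break, not a modelling claim. Patients still in the queue when the
20-year window closes are censored in place: waiting costs accrue to the
horizon but no TKA is recorded (`horizon_queue_policy = "force_tka"` records
one at the horizon instead; the window gives no rule, so censoring — the
choice that invents no event — is the default).

## Cost accounting

Traditional per-patient cost = waiting cost + transplantation cost +
post-transplantation cost; the 3DP version drops the waiting term. Patient
evaluation costs are negligible and ignored. Waiting costs $30 per completed
week in the queue (a timed-out patient accrues all 104 charges). The
traditional transplantation fee is $8,875, of which $4,750 is the allograft;
the 3DP fee replaces the allograft with the $3,124 printed implant (bill of
materials in `implant_bom()`), giving $7,249. Post-transplant states are
charged per entry at the annual check; `TKA` is charged exactly once,
whether reached through the Markov chain or through a queue timeout, and
timed-out patients never pay a transplantation fee. No discounting is
applied — the cost model defines none — and all events after the 1,040-week
horizon are dropped. Calendar year `y` covers weeks `(52(y-1), 52y]`; the
measure-zero week-0 event belongs to year 1.

## Replications, seeding and common random numbers

An experiment averages 10 independent replications (arithmetic mean per
year, with standard errors attached for diagnostics). A master seed spawns
one substream seed per replication; within a replication the patient stream
is drawn first and the per-patient transition uniforms are drawn as one
fixed-size block, so two configurations sharing a master seed share patient
arrivals and per-patient draws position-by-position. Sensitivity sweeps
exploit this: scenario differences are evaluated under common random
numbers, which makes the quality ordering of final-year TKA counts exact in
practice — a larger factor maps each shared uniform to an equally or more
severe destination, never a milder one.

## Numerical choices

* Row-stochasticity is enforced at construction to `1e-9`; probabilities are
  doubles and the scaled `NI` entry is the exact complement of the scaled
  adverse mass.
* The worst-case combined factor is carried as the exact product
  `1.50 * 0.95 * 1.43 = 2.03775` (its two-decimal rendering is 203.78%).
* Cost totals are plain double sums; the per-patient and vectorized
  accumulation paths agree to well below a cent and are tested against each
  other on a full replication.
* Degenerate inputs are contracts, not silent fallbacks: stepping from
  `TKA`, scaling by an infeasible factor, a trajectory attached to a
  timed-out patient, or a non-stochastic matrix all raise errors.

## Problem sizes

The study-scale runs (1,040 patients, 20 years, 10 replications, nine
scenarios) complete in a few seconds, so the test suite and the
reproduction script run them at full scale; unit tests use smaller cohorts
(50–300 patients) where the property under test does not depend on scale.

## Worked example

```{r, fig.width = 7, fig.height = 3.5}
trad <- run_experiment(simulation_config("traditional", seed = 1))
glance(trad)
autoplot(trad)
```

```{r, fig.width = 7, fig.height = 3.5}
sens <- run_sensitivity(simulation_config("3dp", seed = 1))
glance(sens)[, c("scenario", "factor", "cum_tka_total", "cum_cost_musd")]
autoplot(sens)
```

## Known limitations

* No donor–patient compatibility, queue priority scoring, or geography; the
  matching step is absorbed into the donor arrival rate.
* No patient covariates, no utilities or QALYs, no discounting, no
  time-varying transition probabilities.
* TKA is terminal: revision arthroplasty and post-TKA care are out of model.
* The transition probabilities and costs are fixed inputs taken as given;
  the package estimates nothing from follow-up data.
* The waiting-driven share of TKAs is highly sensitive to the donor arrival
  rate, which is the weakest-identified input: with a 3-week mean donor gap
  against a 1-week patient gap, most simulated patients time out, so
  queue-side results should be read as illustrating the shortage mechanism
  rather than forecasting its magnitude.
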