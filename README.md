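# menisim

Monte-Carlo micro-simulation of meniscus transplantation pathways, for
health-economic comparison of the traditional donor-allograft paradigm with
a 3D-printing-enabled (3DP) paradigm in which a patient-matched implant is
printed on demand. It is written for health-economics and operations
researchers who want a transparent, fully seeded implementation of the
pathway model: every assumption is a documented function argument, every
output a tibble.

## The model

Patients arrive as a Poisson stream (mean interarrival 1 week; 1,040
patients over a 20-year window). In the traditional paradigm they join a
first-come-first-served queue for an allograft; donors arrive as a mixed
exponential renewal process (gap mean ~ Uniform(1, 5) weeks), and a patient
who waits 104 weeks is forced into total knee arthroplasty (TKA). In the
3DP paradigm transplantation happens at arrival and the queue disappears.

Post-transplant health follows an annual-cycle Markov chain over the states
no-issue (NI), repair (R), reoperation (RO) and TKA (absorbing), starting
from NI with kernel

| from \ to | NI | R | RO | TKA |
|---|---|---|---|---|
| NI | 0.82 | 0.04 | 0.12 | 0.02 |
| R | 0.80 | 0 | 0.20 | 0 |
| RO | 1 | 0 | 0 | 0 |
| TKA | 0 | 0 | 0 | 1 |

with one cap: the third entry into an intermediate state (R or RO) becomes
TKA. Costs: $30 per waiting week, $8,875 per traditional transplantation
($4,750 of it the allograft), $7,249 per 3DP transplantation (allograft
replaced by the $3,124 printed implant), and per-event charges of
$2,760 (R), $1,770 (RO) and $14,167 (TKA). Implant quality is explored by
scaling all R/RO/TKA transition probabilities by a factor per scenario
(mechanical performance 150%/50%, shape fidelity 95%/90%, biocompatibility
143%/111%, combined 203.775%/49.95%), renormalising through NI.

The package also ships an exact analytic oracle for the capped chain
(`tka_probability_by_cycle()`, an entry-count-augmented kernel) used to
validate the simulation engine.

## Worked example

```r
library(menisim)

trad <- run_experiment(simulation_config("traditional", seed = 1))
trad
#> Pathway experiment: traditional (scenario original), 1040 patients, 10 reps
#> Year 20: 699.4 TKA (595.8 waiting + 103.6 post), cost $16.58M

dp <- run_experiment(simulation_config("3dp", seed = 1))
dp
#> Pathway experiment: 3dp (scenario original), 1040 patients, 10 reps
#> Year 20: 322.2 TKA (0.0 waiting + 322.2 post), cost $14.13M
```

Reading: over 20 years the traditional pathway sends 699 of 1,040 patients
to TKA — 596 of them while still waiting for an allograft, because donors
arrive on average every 3 weeks against one patient per week — at a
cumulative gross cost of $16.6M, while the 3DP pathway (same transition
matrix, immediate transplantation) produces 322 TKAs and costs $14.1M.

Quality sensitivity, under common random numbers across scenarios:

```r
sens <- run_sensitivity(simulation_config("3dp", seed = 1))
glance(sens)[, c("scenario", "factor", "cum_tka_total", "cum_cost_musd")]
#>   scenario  factor cum_tka_total cum_cost_musd
#>   original 1.00000         322.2          14.1
#>   s1       1.50000         484.6          16.8
#>   s2       0.50000         133.0          10.7
#>   s3       0.95000         303.2          13.8
#>   s4       0.90000         282.9          13.5
#>   s5       1.43000         465.7          16.5
#>   s6       1.11000         362.1          14.8
#>   s7       2.03775         599.3          18.7
#>   s8       0.49950         132.6          10.7
```

Final-year TKA counts are monotone in the quality factor: a best-quality
implant (s8) cuts the TKA count to less than half of the original-quality
case and saves a further $3.4M, while the worst case (s7) nearly doubles
the TKA count and pushes the 3DP cost past the traditional paradigm's.

`tidy()` returns the yearly series, `autoplot()` draws the cumulative TKA
and cost curves, and `inst/cli/menisim.R` exposes `simulate`, `sensitivity`
and `implant-cost` subcommands for shell use, writing tidy CSVs plus a
run-metadata JSON.

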