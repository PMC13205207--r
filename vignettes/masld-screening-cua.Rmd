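---
title: "Modelling the cost-utility of WHtR-based two-stage MASLD screening in children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-utility of WHtR-based two-stage MASLD screening in children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masldcea)
```

## The decision problem

Metabolic dysfunction-associated steatotic liver disease (MASLD) is now
common in school-aged children, yet most cases go undetected until fibrosis
has progressed. The waist-to-height ratio (WHtR), available from routine
school physical examinations, is a cheap first-stage filter: children with
WHtR ≥ 0.48 are referred to a confirmatory second-stage test. `masldcea`
models four strategies for a hypothetical cohort of 100,000 children aged
6–14:

* **S1** — WHtR followed by abdominal ultrasound,
* **S2** — WHtR followed by FibroScan (CAP ≥ 249 dB/m),
* **S3** — WHtR followed by MRI proton-density fat fraction,
* **S4** — no screening (reference).

Children confirmed positive enter a lifestyle-modification program (diet and
exercise). The analysis takes a healthcare-system perspective in 2019 USD,
discounts costs and QALYs at 3% per year over a 10-year horizon, and judges
strategies by the incremental cost–utility ratio

$$\mathrm{ICUR} = \frac{C_1 - C_2}{U_1 - U_2},$$

compared with willingness-to-pay (WTP) thresholds of \$30,584.0 and
\$71,415.5 per QALY (three times national and Beijing GDP per capita).

## Model structure

### Decision tree (one-off, cycle 0)

For each age *a* the cohort splits by WHtR result. The WHtR-positive
fraction is fixed at 22.6% (from national survey data). Disease prevalence
among WHtR-positives is reconstructed as

$$\pi^+ (a) = \frac{\pi(a)\,\sigma_1}{0.226},$$

where $\sigma_1$ is the sensitivity of the WHtR stage. The published
material gives the positivity rate but not $\sigma_1$; because the 0.48
cut-off was chosen in prior work to capture essentially all cases, the
package defaults to $\sigma_1 = 1$, so no diseased child is WHtR-negative in
the base case. $\sigma_1$ is a configurable input, and an implied
$\pi^+ > 1$ (prevalence incompatible with positivity) is a configuration
error rather than a silent cap.

The second stage is the usual 2×2 decomposition with the test's sensitivity
and specificity; true positives split into responders (response rate
$\rho = 40\%$) and non-responders. Cost conventions, chosen once and
documented here:

* routine physical examination (\$2.9) is charged to every child under
  S1–S3 and to no one under S4;
* the second-stage image and the blood biochemical panel (\$22.5) are
  charged to every WHtR-positive (the MASLD definition requires
  cardiometabolic criteria, so the panel accompanies the image);
* false positives attend the lifestyle program — they accrue program costs
  for its full duration and disease-free utility, and never transition;
* screening happens once at cycle 0, undiscounted; there are no repeat
  rounds and uptake is 100%.

### Markov model (annual cycles)

Five fibrosis states F0–F4 (F4 read as compensated cirrhosis). Transitions
are tridiagonal: each year a child remains, progresses one stage, or
regresses one stage. Natural-history progression probabilities are
sex-specific; regression is 6% per year in every non-F0 state. The
intervention (responders only) replaces regression with 27.7% — the annual
regression observed under standard diet-and-exercise advice in a pediatric
NAFLD trial — leaving progression unchanged. We read that figure as an
annual probability, the plain reading of its source; alternative readings
can be explored by overriding `transitions.regression_tx` in the config.

Two deliberate simplifications, both documented limitations: there is no
death state (10-year mortality in this age band is negligible and the
published model likewise excludes it), so mass is conserved exactly at every
cycle; and there is no half-cycle correction — states are read at cycle
boundaries and utilities accrue at the end of each cycle, the life-table
convention. QALYs therefore accrue over cycles $t = 1..H$ with factor
$(1+r)^{-t}$, and one child alive for 10 undiscounted cycles at utility 1
contributes exactly 10 QALYs, which the tests assert.

Disease-free children (true negatives, false positives, healthy
WHtR-negatives) carry utility 1.0. Because disease status is identical
across strategies, this value cancels from every incremental comparison;
only its existence as a constant matters.

### Scenario flags

* discount rate 0% / 5%;
* response rate 30%–100%;
* advanced-fibrosis response: intervention regression in F3/F4 scaled by
  0.75 (limited mobility in advanced disease);
* adolescent transitions: from attained age 15, progression ×1.25 and
  regression ×0.75. The direction is supported by the literature; the
  magnitude is not printed anywhere, so ±25% is this package's declared
  default and is reported with any results that use it;
* horizons of 1 and 5 years;
* lifestyle-program duration: the program's fixed (\$10.5) plus variable
  (\$21.7) annual costs are charged per participant for the full horizon by
  default. The duration is genuinely unreported; charging it recurrently is
  the conservative choice, since the program carries all the benefit. A
  `program_duration_years` knob allows 1-year up to full-horizon costing.

## Parameters and uncertainty

Every probability or utility carrying a 95% interval is Beta-distributed in
probabilistic sensitivity analysis. The source material names the Beta
family but no fitting rule, so the package uses a method-of-moments fit on a
normal-approximate standard deviation,

$$\sigma = \frac{\mathrm{CI}_{hi} - \mathrm{CI}_{lo}}{2 \times 1.96},
\qquad \alpha = m\left(\frac{m(1-m)}{\sigma^2} - 1\right),
\qquad \beta = (1-m)\left(\frac{m(1-m)}{\sigma^2} - 1\right),$$

which is simple, reproducible and standard in cost-effectiveness practice.
The fitted distribution has analytic mean equal to the printed mean;
asymmetric intervals are honoured only through $\sigma$ (exact CI-matching
optimisation is deliberately out of scope). A zero-width interval is a
fixed value and signals as such; an interval wide enough that
$\sigma^2 \ge m(1-m)$ is rejected as an invalid fit. Costs are fixed in PSA
(their rows carry no distribution). The F1 and F2 utilities come from one
source and are drawn as a single shared parameter.

```{r beta-example}
beta_from_ci(0.72, 0.64, 0.79)   # FibroScan sensitivity
```

## The synthetic prevalence profile

The one input that is not printed anywhere is the age-specific MASLD
prevalence (derived in the source material by a meta-regression whose output
is not reproduced). The package therefore generates a clearly labelled
synthetic profile, logistic-linear in age:

$$\operatorname{logit} \pi(a) = \operatorname{logit}(0.05) + 0.08\,(a - 6),$$

rising from 5.0% at age 6 to 9.1% at age 14 — a plausible band for Chinese
pediatric MASLD given rising obesity with age. Every report header flags
the profile as synthetic. Consequences:

* all *absolute* dollar and QALY figures are conditional on this profile;
* the *exact-arithmetic* checks (worked-example ICURs, table consistency)
  are independent of it;
* the *qualitative* findings — the frontier ordering S4 → S2 → S3 with S1
  extendedly dominated, S2 optimal at the national threshold and S3 at the
  Beijing threshold, short horizons never cost-effective, and the CEAC
  crossover S4 → S2 → S3 — are asserted as directional checks over a band
  of prevalence baselines (0.03–0.08), not as printed-number matches.

What the generator does *not* emulate: cohort composition is uniform over
ages with a 50/50 sex split (unreported in the source; both are config
knobs); prevalence is deterministic rather than drawn with meta-analytic
uncertainty; and no correlation between prevalence and test performance is
modelled. Passing tests therefore demonstrate internal correctness and
qualitative robustness, not calibration to Beijing's true epidemiology.

## Validation: microsimulation oracle

The deterministic cohort engine is validated against an independent
per-individual microsimulation: 2,000 individuals sampled from the initial
stage distribution, each transitioning annually by categorical draws from
the same matrix rows. Per-cycle occupancies must agree within 3 binomial
standard errors (plus a 0.5/n continuity allowance for the resolution of an
empirical fraction), and mean discounted QALYs within 3 standard errors —
for natural history, intervention, and every scenario-flag combination.
The problem sizes (n = 2,000, 10 cycles, 1,000 PSA iterations, 400-iteration
CEAC check) were chosen so the full validation suite runs in about a minute
while keeping Monte Carlo noise well below the tolerances.

## Numerical conventions

* State vectors and transition-matrix rows must sum to 1 within 1e-12.
* Cohort stratification uses largest-remainder rounding (ties by stratum
  order), so stratum counts always total the cohort size exactly.
* The frontier is computed twice — by dominance pruning plus an ICUR walk,
  and by net-monetary-benefit maximisation — and the two must agree; an
  exact NMB tie (step ICUR equal to the threshold) resolves to the more
  effective strategy, matching the "ICUR ≤ WTP" rule. In acceptability
  curves, per-iteration NMB ties resolve toward the cheaper strategy.
* An ICUR with zero QALY difference is flagged `undefined`, never a
  division error, and dominance quadrants are labelled so a negative ratio
  is not misread as a price.
* PSA draws all parameters up front from one seed; structurally invalid
  draws (progression + regression > 1) are redrawn and counted, preserving
  reproducibility. All randomness flows from one master seed through named
  sub-streams (`substream_seed`), so each analysis is independently
  reproducible.
* YAML configs round-trip at numeric tolerance (1e-12), not bitwise —
  decimal serialisation costs the last ulp.

## Worked example

```{r base-case, eval = FALSE}
params <- default_parameters()
bc <- run_base_case(params)
bc$table
bc$frontier$national$optimal   # "S2"
bc$frontier$beijing$optimal    # "S3"

psa <- run_psa(params, n_iter = 1000, seed = 1)
cc <- ceac(psa)
plot_ceac(cc)
```

## Known limitations

Beyond the synthetic prevalence: no mortality, HCC, decompensation or
transplantation states; no complications (type 2 diabetes, cardiovascular
disease), so utility losses are understated and ICURs conservatively
overstated; adult-derived utilities applied to children; no waning of
lifestyle-program effect; no screening adherence below 100%; no parameter
correlations in PSA; and transition evidence concentrated in two published
natural-history studies.
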