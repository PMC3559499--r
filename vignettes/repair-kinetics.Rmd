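---
title: "Modelling single- and double-strand-break repair in a circular minichromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single- and double-strand-break repair in a circular minichromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairkinetics)
```

## The system and the model

After ionising irradiation, a ~172 kb closed-circular minichromosome (the
Epstein–Barr virus episome, maintained at 50–100 copies per nucleus) carries
a mixture of single-strand breaks (SSBs, nicks) and double-strand breaks
(DSBs). A DSB linearises the circle; SSBs relax it. On a pulsed-field gel
this yields four molecular forms, of which two are quantitated directly:

| form   | topology                          | PFGE band            |
|--------|-----------------------------------|----------------------|
| `S`    | supercoiled circle, no breaks     | supercoiled band     |
| `L`    | full-length linear, DSB only      | linear band          |
| `LSSB` | linear, DSB plus SSBs             | linear band (co-migrates with `L`) |
| `CSSB` | nicked circle, SSBs only          | not quantitated      |

Repair interconverts these forms. Because repair of *all* the SSBs in a
molecule (or of its single DSB) moves the whole molecule between forms, the
kinetics are modelled as first-order transfers of molecule fractions, not of
individual breaks:

$$
\begin{aligned}
\frac{dS}{dt} &= \kappa_d\,L + k_s\,\mathit{CSSB} \\
\frac{dL}{dt} &= k_{sd}\,\mathit{LSSB} - \kappa_d\,L \\
\frac{d\,\mathit{LSSB}}{dt} &= -(k_{sd} + \kappa_{ds})\,\mathit{LSSB} \\
\frac{d\,\mathit{CSSB}}{dt} &= \kappa_{ds}\,\mathit{LSSB} - k_s\,\mathit{CSSB}
\end{aligned}
$$

with $\kappa_d = k_d \cdot \mathit{hr} \cdot s_{inh}$ and
$\kappa_{ds} = k_{ds} \cdot \mathit{hr} \cdot s_{inh}$. The four rate
constants (per hour) are: $k_d$, repair of the DSB in `L`; $k_s$, repair of
all SSBs in `CSSB`; $k_{ds}$, repair of the DSB in `LSSB`; $k_{sd}$, repair
of all SSBs in `LSSB`. This transition topology — `LSSB` drains into both
`L` (SSBs fixed first) and `CSSB` (DSB fixed first), which both drain into
the absorbing supercoiled pool — is the unique arrangement consistent with
the verbal definitions of the four rates, and it reproduces the predicted
long-horizon behaviour under both normal repair and DSB-repair arrest (see
below).

Two scenario parameters modify the effective rates without touching the
fitted constants. $s_{inh} \in \{0, 1\}$ switches DSB repair off entirely
(0 when DNA-PKcs is inhibited by NU7441 or wortmannin, which arrests DSB
repair; 1 otherwise). $\mathit{hr} \in (0, 1]$ scales DSB repair down to
model partial suppression of homologous recombination: ATM inhibition by
KU55933 or caffeine slows the loss of linear DNA by ~30%
($\mathit{hr} = 0.70$), mirin by ~26% (0.74) and Rad51 depletion by ~20%
(0.80). PARP-1 inhibitors (NU1025, 1,5-IQD) and catalytic topoisomerase
inhibitors (ICRF-193, F11782) measurably change nothing and map to the
identity scenario. The registry `INHIBITOR_REGISTRY` makes each of these
named actions total and unambiguous.

Mass is conserved exactly: the four derivatives sum to zero, so
$S + L + \mathit{LSSB} + \mathit{CSSB} = 1$ at all times. The observation
operator collapses the latent state onto the two measured bands,
$\text{linear\_total} = L + \mathit{LSSB}$ and $\text{supercoiled} = S$;
the nicked-circle level is recovered only through the model, which is the
original motivation for building it.

### Solving the system

The system is linear with constant coefficients and triangular structure,
so `solve_repair()` evaluates a closed-form cascade of exponentials: `LSSB`
decays at $\beta = k_{sd} + \kappa_{ds}$, and the feeds into `L` and `CSSB`
are convolution terms of the form
$(e^{-at} - e^{-\beta t})/(\beta - a)$. These are computed through
`expm1()` so that nearly degenerate rate pairs ($\beta \to a$) lose no
precision; the exact limit $t e^{-at}$ is used at equality. An independent
numerical route (`deSolve::ode`, lsoda, rtol $10^{-9}$, atol $10^{-12}$)
is retained purely as a cross-check; the two agree to better than
$10^{-8}$ across random parameter draws, which is what makes the
$10^{-9}$ conservation bound testable.

```{r trajectory}
rates <- rate_constants(k_s = 0.21, k_d = 0.74)
init <- compartment_state(L = 0.05, LSSB = 0.95)
traj <- solve_repair(rates, scenario("control"), init, seq(0, 2, 0.25))
head(observe(traj))
```

## Fitting: what is estimated and how

`fit_repair()` minimises the sum of squared residuals between the model
observables and every replicate measurement, jointly across conditions.
The canonical design has two arms that share everything except the switch:
normal repair ($s_{inh} = 1$) and NU7441 arrest ($s_{inh} = 0$). Rates and
the initial state are shared across arms — both come from the same
irradiated population — though `share_init = FALSE` fits per-condition
initial states if the populations genuinely differ.

Numerical choices:

* **Positivity** is enforced by fitting $\log k$ (box bounds
  $[10^{-4}, 50]$ per hour, far outside any plausible estimate).
* **The initial state** is parameterised on the 3-simplex by
  stick-breaking from three variables in $[0,1]^3$, so every iterate is a
  valid composition; no penalty terms are needed.
* **Optimisation** is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`)
  restarted from `n_starts` uniform random starting points (rates
  log-uniform on $[0.01, 10]$ per hour), seeded and fully deterministic
  given the seed. The best start is reported; the whole multistart trace
  is kept because it is the raw material of the identifiability
  diagnostics.
* **Replicates** enter the objective individually, not as means, so
  precision differences between cells propagate into the fit naturally.

On noiseless synthetic data the tied fit recovers generating rates
anywhere in $[0.05, 2]$ per hour to better than $10^{-3}$ relative error.
A caveat found during development and reflected in the defaults: for some
rate pairs the global basin of attraction is narrow and a few dozen random
starts are needed; `n_starts = 100` is the default and costs about a
second on this problem size.

### Why the rates are tied

With only two observed bands, freeing all four rates gives a model whose
parameters trade off against each other. `identifiability_scan()`
diagnoses this the way the original analysis experienced it: refit from
many random starts and see whether distinct, far-apart parameter sets fit
the data equally well. Two conventions needed fixing, and both are package
choices:

* **The near-optimal band.** A start counts as "fitting equally well"
  when its SSR lies inside the classical F-contour of nonlinear least
  squares, $SSR \le SSR_{best}\,(1 + \tfrac{p}{n-p} F_{0.95}(p, n-p))$,
  plus an absolute floor of $10^{-9}$ so the band is meaningful when the
  best fit is numerically exact. A fixed small percentage band would be
  blind to optima separated by a few percent of SSR on noisy data while
  being vacuous on noiseless data.
* **The dispersion flag.** A rate is flagged non-identifiable when its
  near-optimal estimates span more than a decade (max/min > 10).
  Non-identifiable parameters collapse onto the box bounds or trade off
  by orders of magnitude; ordinary sampling uncertainty of an
  identifiable rate — the published 95% CI for $k_s$ spans roughly
  $\pm 25\%$ — stays far inside a decade, so a percentage-scale threshold
  would conflate the two.

Under the study conditions (noise sd 0.03, three replicates, five time
points, two conditions) the four-rate scan flags the model on the large
majority of simulated datasets (9 of 10 generator seeds during
development, with near-optimal parameter ranges of 2–4 decades), while
the tied model is never flagged (ranges below 0.2 decades). Occasional
noise draws genuinely pin all four rates; practical identifiability is a
property of data, not only of structure.

## Confidence intervals

The CI method is a parametric bootstrap: simulate `n_boot` datasets from
the fitted model with Gaussian noise at the residual scale (root mean
square residual), truncated at zero exactly like real band fractions,
refit each from the point estimate, and summarise the refit distribution.
The reported interval is
$\hat k \pm t_{0.975,\,n-p}\,\mathrm{SE}_{boot}$, centred on the point
estimate; the raw 2.5/97.5 bootstrap percentiles are returned alongside.
Centring matters here: zero-truncation of noise near empty bands skews
the refit distribution, and in a 100-dataset calibration at the study
conditions the percentile interval covered the generating $k_d$ only 83%
of the time, the basic interval covered $k_s$ only 77%, while the
SE-based interval covered both at ~90%. With a zero-residual fit the
intervals degenerate to the point estimate, as they should.

```{r ci}
d <- generate_dataset(reference_config(seed = 11))
fit <- fit_repair(d, n_starts = 20, seed = 1)
fit <- bootstrap_ci(fit, d, n_boot = 200, seed = 2)
fit$ci
```

## The synthetic-data generator

`generate_dataset()` is the package's stand-in for gel quantitations that
exist only as figure panels; no replicate-level measurements were ever
published, so nothing here claims to reproduce them — only the fitted
parameters and the qualitative behaviour. The generator solves the model
exactly, applies the observation operator, and adds i.i.d. Gaussian noise
per replicate on the fraction scale, truncated to the validated
measurement range $[0, 1.1]$. Its defaults *are* the study conditions:

* rates $k_s = k_{sd} = 0.21$, $k_d = k_{ds} = 0.74$ per hour (the
  published estimates);
* initial state $\mathit{LSSB} = 0.95$, $L = 0.05$: immediately after
  50 Gy essentially every molecule is linearised and S1-sensitive, so
  nearly all mass starts in `LSSB`; the 5% SSB-free linear fraction is a
  fixture convention, and fits re-estimate the initial state regardless;
* times $\{0, 0.5, 1, 1.5, 2\}$ h — the experiments span two hours and
  the exact sampled times are not printed, so an even grid is used;
* three replicates, matching the reported "SEM from three independent
  experiments";
* noise sd 0.03 on the fraction scale — the figure error bars are not
  numerically printed; 0.03 is a realistic gel-quantitation scatter and
  is configurable.

What the generator does **not** emulate: correlated errors within a gel,
background-subtraction artefacts, signal nonlinearity, or any dose
response beyond the 50 Gy reference. Passing tests therefore demonstrate
correctness of the estimator on data satisfying the model's error
assumptions, not robustness to every failure mode of real gels.

## Molecule-level break simulation

`induce_breaks()` draws DSB and SSB counts per molecule (defaults: exactly
one DSB — a Poisson DSB model is deliberately *not* the default, since
quantitative conversion to full-length linear DNA indicates one
non-specific DSB per molecule at 50 Gy — and Poisson(8.5) SSBs, matching
the observed "8 to 9 breaks") and places them uniformly on the circle.
`s1_fragments()` opens the circle at the DSB and cuts at every SSB: n SSBs
give n + 1 fragments summing to 172 kb, so the mean fragment length of
$172/(n+1)$ kb inverts to the break count. `estimate_ssb_count()` reports
both inversion conventions ($172/\bar\ell$ and $172/\bar\ell - 1$, the
published "8 to 9" not stating which was used) plus the flanking-integer
midpoint. Limitations, by design: positions are continuous with no strand
assignment (the assay cannot resolve strand), so closely spaced opposite-
strand SSBs that would behave as a de facto DSB are not modelled.

## Derived times and the 20-hour prediction

`half_time()` reports $\ln 2 / k$ in minutes: 56.2 min for
$k_d = 0.74$/h and 198.0 min for $k_s = 0.21$/h. The original analysis
quotes ~40 min and ~140 min half-times read at the data scale; these do
not equal $\ln 2/k$ and the procedure behind them is not stated, so the
package reports the first-order values and leaves the discrepancy
documented rather than guessed at. The per-break arithmetic uses the
measured overall half-time: `per_break_repair_time(140, 8.5)` ≈ 16.5 min
per break.

Extrapolating the fitted rates to 20 h reproduces the predicted shapes:
under normal repair the nicked-circle pool rises transiently and drains
as supercoiled DNA approaches 1; under DSB-repair arrest no nicked
circles form and SSB-free linear DNA accumulates monotonically toward 1.

```{r extrapolate, fig.width = 6, fig.height = 4}
plot(extrapolate_repair(rates, scenario("control"),
                        compartment_state(LSSB = 1), horizon = 20))
```

## Problem sizes used in the test suite

The shipped tests exercise: conservation and exact-vs-numeric agreement
on 20–25 random parameter draws over a 20 h grid; tied-model recovery on
5 random rate pairs (60 starts each); bootstrap coverage on 100 noisy
datasets with 100 bootstrap refits each; identifiability scans with
60–100 starts; and fragmentation statistics on populations of 10^4
molecules. These sizes give stable verdicts for every property while the
whole suite completes in a couple of minutes.

## Known limitations

* The model is a population-average first-order description; it carries
  no per-break sub-model, no chromatin context, and no Michaelis–Menten
  saturation (first-order transfer was an explicit modelling commitment,
  and the data do not constrain more parameters).
* The nicked-circle compartment is never observed; everything said about
  it is model-mediated.
* `hr_factor` is a phenomenological scalar on DSB-repair rates, not a
  mechanistic HR/NHEJ competition model.
* The generator's noise model is the simplest one consistent with the
  reported error bars; see above for what it omits.
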