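---
title: "Predicting skin irritation from impedance spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting skin irritation from impedance spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheis)
```

## The measurement and the statistic

A reconstructed human epidermis (RhE) insert is electrically a stack of
conductive media (culture medium, intra/extracellular electrolyte)
separated by insulating lipid structures (cell membranes, the stratum
corneum). An impedance sweep — 25 logarithmically spaced frequencies from
1 Hz to 1 MHz, small AC excitation — therefore carries structural
information. The pipeline reduces each sweep to the *apparent
capacitance*

$$C(f) = \frac{1}{2 \pi f \, |Z''(f)|},$$

the capacitance a pure capacitor would need to produce the observed
reactance. Capacitive reactance is negative by convention, but input files
use both sign conventions, so the magnitude of $Z''$ is taken; this is the
only deviation from the plain formula and it only ever affects the sign,
never the value. A reactance of exactly zero has no capacitive
interpretation and raises a degenerate-spectrum error naming the offending
frequency.

Tissues differ in geometry and baseline barrier quality, so raw
capacitance is not comparable across inserts. The working quantity is the
per-tissue normalized capacitance

$$R(f, t) = \frac{C_x(f, t)}{C_0(f)},$$

the ratio of a tissue's post-exposure capacitance to *its own*
pre-exposure (time-0) sweep at the same frequency. Using the tissue's own
baseline, never a group mean, cancels inter-tissue scale differences
exactly; any common rescaling of a tissue's impedance cancels in the
ratio.

Barrier disruption by an irritant raises $R$ strongly, with a maximum at
an intermediate frequency: at low frequency the response is dominated by
resistive paths, at high frequency the intact and damaged tissue converge
to similar series-capacitance behaviour, and in between the loss of the
stratum-corneum barrier is maximally visible. The analysis frequency is
chosen as the grid point maximizing the *mean* normalized capacitance of
the positive-control tissues at the latest measured time (configurable to
all treated tissues; the pooled-time variant is supported by passing the
subset explicitly). On the canonical grid $10^{k/4}$ Hz, $k = 0..24$ —
the only 25-point logarithmic grid spanning exactly 1 Hz–1 MHz — the peak
falls on $10^{4.25} \approx 17.8$ kHz, which is also where the nominal
label "17 kHz" lands via log-scale nearest-point mapping
(`nearest_grid_frequency()`). All argmax-style selections break ties
toward the lower frequency, deterministically.

## Classification and validation

Scores are aggregated hierarchically: a run's score for a chemical is the
mean over its (typically three) replicate tissues; the chemical's overall
score is the mean of run means. This mirrors how replicate tables are
reported and keeps run-level calls available for reproducibility scoring.
Replicate-level classification remains possible by passing tissue scores
directly.

The decision rule is *irritant iff score ≥ cut-off*. The boundary
convention (≥, not >) cannot be resolved from published summary values,
which never land exactly on a cut-off; ≥ is chosen so the positive
control remains an irritant under every reported cut-off. The MTT
comparison rule is *irritant iff relative viability < 50%*, strictly, as
the guideline types it.

ROC analysis uses the empirical curve with one vertex per distinct score
plus the two degenerate endpoints. AUC is computed as the Mann–Whitney
pair statistic — the fraction of (irritant, non-irritant) pairs ranked
correctly, ties counting 0.5 — which equals the trapezoidal area under
the empirical curve to numerical precision (a property the test suite
checks on 1 000 random instances) and is invariant under strictly
increasing transforms of the scores. The accuracy-optimal cut-off is
reported as the *full interval* of equivalently optimal values: accuracy
as a function of the cut-off is piecewise constant on half-open intervals
between observed scores, so the optimum is an interval $(lo, hi]$ whose
endpoints are observed scores; candidates examined are the distinct
scores, midpoints of consecutive scores, and points outside the observed
range. The lower endpoint is the reported representative; when the
pipeline needs a single operating cut-off ("auto"), it uses the interval
midpoint, which is safely interior.

Performance is summarized with Category 2 as the positive class.
Sensitivity or specificity with an empty class is reported as undefined
(`NA`), never 0. The OECD TG 439 compliance flag requires sensitivity
≥ 80%, specificity ≥ 70% and accuracy ≥ 75%. Within-laboratory
reproducibility is the percentage of chemicals whose runs all yield the
identical call; it requires a balanced run structure and names the
discordant chemicals.

Run qualification is applied before prediction, with the printed bounds
applied exactly as typeset: TEER in [600, 2500] Ω·cm² per tissue
(out-of-range tissues are discarded), negative-control OD in
[0.40, 0.70], positive-control viability < 50% (a failing control
invalidates every chemical in the run), and replicate viability SD ≤ 18
(strictly above 18 triggers a per-chemical retest). Whether TEER bounds
apply per tissue or per run mean is not specified in the source
guidance; per-tissue is implemented, matching the discard-the-model
wording. The SD-based retest criterion is defined for viability only; an
analogous capacitance-based criterion exists behind an explicit call but
is not applied by default.

## The synthetic study generator

No raw impedance data are publicly deposited, so the package generates
its own studies from a physically motivated forward model. The tissue is
a series resistance plus two parallel R‖CPE blocks:

$$Z(\omega) = R_s
  + \frac{R_{sc}}{1 + (j\omega R_{sc} C_{sc})^{\alpha_{sc}}}
  + \frac{R_{ve}}{1 + (j\omega R_{ve} C_{ve})^{\alpha_{ve}}}.$$

Two blocks are the minimal topology whose normalized-capacitance ratio
has an interior frequency peak: for a single R‖RC block the ratio is
monotone in frequency (for $\alpha = 1$ the apparent capacitance has the
closed form $C + 1/(\omega^2 R^2 C)$, which the tests verify), so no
single-block model can reproduce a mid-band maximum.

Chemical damage is barrier disruption: at damage level $d$ the
stratum-corneum block changes to $R_{sc}(1 - 0.95 d)$ and
$C_{sc}(1 + k_c d)$ with $k_c = 30$; the viable-epidermis block is
untouched. Each chemical is an *archetype* $(\text{grade}, \text{lag},
\text{rate})$ with time course
$d(t) = \text{grade}\,(1 - e^{-\text{rate}\,\max(0, t - \text{lag})})$,
so baselines ($t = 0$) are always unperturbed. Non-irritant archetypes
have grade ≤ 0.2, irritants ≥ 0.5; two irritants (CASRN 629-19-6 and
7340-90-1) are delayed responders with lag > 2 h, scoring below 1.5 at
2 h and above 7.5 at 42 h.

Default circuit values ($R_s = 100$ Ω, $R_{sc} = 20$ kΩ,
$C_{sc} = 2$ nF, $\alpha_{sc} = 0.9$, $R_{ve} = 100$ Ω, $C_{ve} = 2$ nF,
$\alpha_{ve} = 0.95$) were calibrated once, before any validation runs
were scored, so that (i) the fully damaged ratio spectrum peaks exactly
on the $10^{4.25}$ Hz grid point, (ii) the positive-control ratio at that
frequency falls in the 20–35 range, and (iii) the grade → ratio
dose-response at 42 h spans roughly 0.8–6 for non-irritant grades and
9–24 for irritant grades, matching the ranges reported for real RhE
tissue. Per-chemical grades were then fixed by inverting this
dose-response against the published 42 h per-chemical means (clipped to
the class constraints); rates and lags shape the 2/24 h time courses
approximately. These are package defaults, not fitting parameters, and
they are not revisited.

A slow common drift $e^{-0.005 t}$ (per hour) multiplies both
capacitances during incubation, reproducing the slight sub-unity ratios
of untreated tissues over 42 h (≈ 0.99 / 0.89 / 0.81 at 2/24/42 h).

Stochastic components, each independently switchable to zero:

- `noise_sd_log` (default 0.05): multiplicative lognormal measurement
  noise per frequency point on $|Z|$ with phase preserved — impedance
  magnitude errors are relative across six frequency decades.
- `tissue_cv` (default 0.10): lognormal inter-tissue variability of the
  baseline circuit elements.
- `grade_cv` (default 0.20): lognormal tissue-level susceptibility
  multiplier on the damage grade (capped so $d \le 1$).
- `run_cv` (default 0.05): run-level susceptibility multiplier, a batch
  effect. Run- and tissue-level variance are separate knobs because
  published summary SDs conflate the two; no particular split is
  asserted.

Reproducibility: one master seed; every tissue and run draws from its own
substream seeded by `master + hash(label) mod (2^31 - 1)` with a stable
string hash, so adding chemicals to a design never reshuffles existing
tissues, and identical designs produce byte-identical CSV output.

What the generator does *not* emulate: electrode polarization and
double-layer effects, Warburg diffusion, temperature drift, chemical
colour/MTT interference, or reversible (recovering) damage. Passing the
recovery tests therefore shows the *pipeline* is correct and the study
design is adequately powered under plausible tissue physics — not that
any particular laboratory's instrument noise matches these defaults.

## Problem sizes and runtime choices

The default study is the full validation layout: 22 conditions
(20 chemicals + 2 controls) × 3 runs × 3 replicates × 4 times × 25
frequencies = 19 800 spectra rows, generated in well under a second. The
stochastic end-to-end check uses 20 independently seeded full studies,
classifying every archetype at cut-off 7.5/42 h; the reproducibility and
performance checks on the bundled reference tables are instantaneous.
These sizes keep the complete test suite in the tens of seconds while
exercising the design at full scale.

## Known limitations

- The bundled reference results are summary tables (run means), not raw
  spectra; replicate-level AUCs reported for the original measurements
  are therefore not exactly recomputable here, and mean-level AUCs are
  used as the documented oracle instead. Two rows of the published
  run-level table are internally inconsistent with their printed
  mean ± SD summaries; the package reproduces the aggregation, not the
  typos.
- The equivalent circuit is a forward model for simulation only; the
  package deliberately does not fit circuits to measured spectra, nor
  does it implement Kramers–Kronig validation or between-laboratory
  reproducibility (no multi-laboratory data exist for this method).
- Sub-categorization of irritancy strength from the 2/24/42 h time
  course is visible in the delayed-responder patterns but is not a
  supported classification output.
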