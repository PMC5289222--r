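---
title: "Growth-rate control of sporulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate control of sporulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthrelay)
```

# The scientific question

Starving *Bacillus subtilis* cells do not sporulate immediately: they pass
through several rounds of vegetative division, slowing down gradually, and
only commit to spore formation when the per-cycle pulse of phosphorylated
Spo0A (0A~P) exceeds a threshold. `growthrelay` implements a quantitative
account of why those pulse amplitudes rise as growth slows: stable proteins
— above all the kinase KinA — accumulate when dilution by growth decreases
and cell volume shrinks, and the lengthening gap between chromosome
replication rounds gives each pulse more room. The growth rate itself then
acts as the starvation signal: cells growing slower than a threshold rate
sporulate, and the multi-generation deferral of sporulation is just the
time it takes the colony's growth-rate distribution to fall below that
threshold.

# Stable-protein accumulation

Exponential volume growth dilutes every protein at the growth rate
$\mu$, so a stable protein produced at rate $P$ reaches steady state

$$C(\mu) = \frac{P}{V(\mu)\,(k_{deg} + \mu)}.$$

With $k_{deg} = 0$ and unit volume this is the textbook arithmetic of
`worked_copy_number()`: 10 molecules/min with a 60-min generation time
gives 600 copies, and 3,000 at 300 min (the effective dilution rate there
is $1/\tau_{gen}$; the $C(\mu)$ law instead uses the natural-log
elongation rate, $\ln 2 / \tau_{gen}$ for steady doubling — the two
conventions are both exposed and never silently interchanged).
Cell volume is cross-sectional area times the division length
$L(\mu) = 3.466\,e^{-0.689/\mu} + 3.743\ \mu m$; the area is fixed, so only
concentration ratios matter and curves are normalised at
$\mu = \ln 2$ per hour.
`fit_degradation_rate()` fits $k_{deg}$ to normalised fold-change data by
unweighted nonlinear least squares (no weighting scheme is imposed on the
inputs; the normalised curve is production-independent, which is why
fold-change data at different induction levels collapse). On clean data the
fit is exact; under 5% multiplicative noise it recovers the truth within
two standard errors in well over 90% of replicates.

```{r copy-numbers}
worked_copy_number(10, 60)
worked_copy_number(10, 300)
```

# The phosphorelay model

The relay KinA → Spo0F → Spo0B → Spo0A is modelled as eight deterministic
ODE species (each protein and its phosphoform, nM) with lumped
transcription–translation, Hill-type 0A~P regulation of the native
promoters, reversible phosphotransfer, first-order dephosphorylation of
0F~P and 0A~P, dilution at $\mu(t)$ on every species, and production
scaled by instantaneous gene dosage and divided by the volume $V(\mu)$
(normalised to 1 at $\mu = \ln 2$/h). Events from the cell-cycle scheduler
(`build_schedule()`) switch gene copy numbers between 1 and 2; symmetric
division leaves concentrations unchanged. Integration is `deSolve::lsoda`
between events (rtol = atol = 1e-8), with dense 0.01-h output for peak
detection.

Three structural choices deserve explanation:

* **Quadratic-plus autophosphorylation.** KinA is only active as an
  oligomer; in the unsaturated assembly regime the autophosphorylation flux
  goes as $k_a K_{dim} (K/K_{dim})^{n_{auto}}$ with $n_{auto} > 2$. This
  superlinearity is what makes the 0A~P pulse amplitude an ultrasensitive
  function of the KinA concentration — and hence of growth rate, because
  stable KinA accumulates as $1/(V(\mu)\mu)$.
* **Substrate inhibition by total 0F.** High Spo0F blocks KinA
  autophosphorylation with a Hill term $1/(1+(F_{tot}/K_I)^{n_I})$. During
  the replication window when the oriC-proximal *spo0F* is duplicated but
  ter-proximal *kinA* is not (dosage ratio 1:2), 0F production runs ahead,
  inhibition deepens and 0A~P dips; when replication completes the ratio
  returns to 1:1 and 0A~P rises — one pulse per replication round. The
  within-cycle trough sits inside the replication period and 0A~P rises
  from completion to division; because the state is periodic across
  symmetric divisions, the attained maximum spans the division boundary.
* **Growth-coupled spo0F transcription.** Native *spo0F* transcription is
  scaled by $\mu V(\mu)/\ln 2$, the growth-rate scaling of the
  gene-expression machinery. The steady 0F level is then essentially
  growth-independent — 0F homeostasis — while KinA, deliberately left
  growth-uncoupled, accumulates. This is what makes the KinA *level*
  threshold for sporulation independent of the KinA production rate while
  the growth-rate threshold moves with it, and it keeps the
  amplitude–growth curve monotone down to very slow growth. Inducible
  P_hsp copies are growth-independent, consistent with the observed
  accumulation of stable inducible reporters.

## Calibration

The paper-level anchors for the relay are the two sensitivity values at a
reference slow growth rate (0.2/h): +10% KinA production raises the
periodic-steady-state peak 0A~P by ≈ 25%, and +10% 0F production lowers it
by ≈ 18%. Two constants with no independent measurement — $n_{auto}$ and
$K_I$ — are calibrated to those anchors by a damped Newton iteration
(`scripts/calibrate.R`); the shipped defaults ($n_{auto} = 2.385$,
$K_I = 1200$ nM) meet both to within 0.1 percentage points. $k_a$ sets the
absolute 0A~P scale (~90 nM at the reference point) and barely affects
either sensitivity. All other constants are round-number choices at
plausible scales (phosphotransfer 0.2 /nM/h with 10:1 forward:reverse
ratio, 0A~P dephosphorylation 30/h, production rates tens to hundreds of
nM/h) fixed before any comparison and not revisited.

```{r sensitivity, eval = FALSE}
relay_sensitivity(phosphorelay_params(), strain_config("WT"),
                  mu_ref = 0.2, target = "kinA", delta = 0.1)   # ~ +25
relay_sensitivity(phosphorelay_params(), strain_config("WT"),
                  mu_ref = 0.2, target = "spo0F", delta = 0.1)  # ~ -18
```

## Strains

`strain_config()` wires the modelled strains. *iTrans-0F* moves the
native-promoter *spo0F* to the same terminus-proximal region as *kinA*
(their dosage ratio then never leaves 1:1 — no pulses without inducer) and
adds an IPTG-inducible copy near oriC whose production restores the
transient imbalance. *inducible-KinA* expresses *kinA* from an inducible,
feedback-free promoter at its native ter-proximal locus; pulsing survives,
which is also how the model shows the 0A~P–KinA transcriptional feedback
is dispensable (`kinA_feedback = "none"`). One known infidelity: without
inducer the model's iTrans-0F sits at a flat, fairly high 0A~P level
(slightly *less* total 0F is made from the relocated locus), so the
experimental observation that this strain does not sporulate without IPTG
is represented here only by the absence of pulses, not by a low absolute
0A~P level. Within-cycle pulse contrast is likewise moderate
(peak/trough ≈ 1.2 at 0.2/h): with stable proteins, pool excursions per
cycle are bounded by the fraction of protein made per cycle, so the
dominant observable is the strong growth-rate dependence of the amplitude,
not a return-to-zero waveform.

# Cell-cycle scheduling

Replication initiates at birth and lasts $T_{rep}(\mu) = 0.15/\mu + 0.78$ h;
a locus at fraction $d$ of the replication arm is duplicated at
$d\,T_{rep}$ (*spo0F* at 34/180, *kinA* at 126/180 on the bidirectional
360° map). Division fires when exponentially integrated length reaches
$L(\mu)$, but never before replication completes (zero D-period); at fast
growth the replication period therefore occupies the whole cycle and the
1:1-dosage window vanishes, which is why pulses are clipped at high $\mu$.
No multifork replication is modelled — starving cells are slow, and the
regime of interest is the opposite one. Event times are located by
root-finding to 1e-9 h. Where in the cycle replication initiates, and the
linear fork-progression law, are assumptions: the data constrain only
$T_{rep}$.

# The synthetic-data generator

`sample_lineage()` grows a binary tree whose per-cycle log growth-rate
deviations follow an AR(1) inheritance with a shared sister component:
mother–daughter correlation $a = 0.41$ and sister correlation
$a^2 + \gamma = 0.36$ fix both parameters (pairs below $a^2$ are rejected
as infeasible). The generation mean relaxes from 0.65/h to a
deep-starvation floor of 0.22/h at rate 0.6/generation, crossing the fate
threshold $\mu^* = 0.25$/h around generation 4–5 so the sporulating
fraction rises from near zero to a ~2/3 plateau — the floor sits just
below the threshold, which is what caps the plateau below 1. Fate is
deterministic in the *true* growth rate (spore iff $\mu \le \mu^*$);
spore branches terminate and end 2 h after their last vegetative span to
exercise the analysis truncation rule.

`render_timelapse()` samples 20-min frames: lengths grow exponentially at
the true rate with two noise layers — frame-to-frame growth fluctuation
(lognormal factor on each increment, sd 0.28) and multiplicative
measurement noise (2%). The growth fluctuation is the modelling choice
that decouples *measured* cycle-mean growth from the true rate that set
the fate, so growth-based fate prediction is good but imperfect
(AUC ≈ 0.92–0.97, accuracy ≈ 0.84–0.93 across seeds) — the regime of real
colonies — instead of a degenerate perfect separator. Fluorescence
accumulates as activity × length, halves at division, and the pulsatile
channel fires a 1-h activity bump after replication completion with
amplitude from a decreasing Hill law in $\mu$ (a phosphorelay
`amplitude_vs_growth()` curve can be substituted). What the generator does
*not* emulate: segmentation errors, photobleaching and maturation,
asymmetric division geometry, non-exponential elongation. Tests passing on
these data therefore validate the pipeline's arithmetic and the
classifier's calibration, not image analysis.

# Quantification pipeline

Growth rates are forward-difference log-derivatives of length (natural
log; the $\mu = \ln 2$/h normalisation point fixes the convention);
cycle means for sporulating cells are truncated at the asymmetric
division (reporter activation, else 2 h before the forespore). Promoter
activity is the time derivative of total fluorescence per unit length
(central differences; one-sided at boundaries) — for a stable reporter,
total fluorescence already integrates production, so its derivative is
the production rate; an optional dilution-correction term
$\mu F/L$ covers concentration-like signals, and neither variant is
asserted to be the historically exact formula. Activity series are
smoothed with a Savitzky–Golay filter (3rd-order, 5 frames — the filter
reproduces cubics exactly, so a smooth pulse is not attenuated) and the
per-cycle maximum is the pulse amplitude.

# Classification and statistics

Fate thresholds come from binomial logistic regression (IRLS via `glm`);
the threshold is $-\beta_0/\beta_1$ (probability 0.5) with a delta-method
standard error from the observed information — the SE convention is a
choice, as is the Wald (rather than likelihood-ratio) test for covariate
effects, matching the coefficient t-tests used in this literature.
Complete separation is flagged, never reported as numbers. ROC curves
sweep all distinct score values with ties grouped and trapezoid AUC.
Spearman correlations are tested with the Fisher-z normal approximation
(variance inflation 1.06), with a permutation option for small n;
`required_n(0.2, 0.9, 0.05)` gives 274, verified by simulation.

# Population model and deferral

The colony model is Monod batch growth
($dN/dt = \mu(S)N$, $dS/dt = -\mu(S)N/Y$) — the simplest closure with the
right qualitative behaviour; the $\mu(S)$ law is a swappable function.
A glucose bolus is an initial-condition change: it delays the crossing of
any growth threshold but steepens the decline once the larger population
exhausts the pool. The deferral predictor is the plug-in estimator: the
predicted sporulating fraction per generation is the fraction of cycles
with mean growth at or below the threshold.

# Numerical choices and problem sizes

Relay integration: lsoda, rtol = atol = 1e-8, 0.01-h output grid; periodic
steady state declared when successive pulse peaks agree to 0.5%
(1e-3 for sensitivity runs), capped at 80 cycles with a convergence flag.
Amplitude–growth curves in examples and tests use 4–6 grid points between
0.08 and 0.65/h; test colonies are single lineages of ~100–200 cells and
the Monte-Carlo checks use 20–200 replicates — sizes chosen so the whole
suite exercises every claim in minutes on one CPU while keeping binomial
test bands meaningful. Known limitations: no stochastic gene expression,
no multifork replication, no explicit mRNA, no Sda/KipI/Rap/Spo0E
checkpoint species (the sda-deletion strain is a label equal to wild
type), and the iTrans-0F caveats above.
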