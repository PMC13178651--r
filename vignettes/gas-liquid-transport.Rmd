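---
title: "Modelling and measuring gas-liquid transport of airway mucus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring gas-liquid transport of airway mucus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gltr)
```

Airway mucus is cleared by coordinated ciliary beating (mucociliary
clearance) and, when mucus accumulates, by the very high airflow
velocities of cough. A third mechanism, cilia-independent **gas-liquid
transport (GLT)**, moves the viscoelastic mucus layer by the shear that
tidal-breathing airflow exerts at the gas-liquid interface. Net cephalad
transport requires expiratory airflow velocity to exceed inspiratory
velocity; this asymmetry arises because airways narrow during exhalation
(airway hysteresis) while the volume flow is the same in both phases.
`gltr` implements the three quantitative stages used to study GLT, plus
synthetic-data generators that carry their own ground truth.

## 1. The airway airflow-asymmetry model

The human tracheobronchial tree is modelled as Weibel's symmetric
dichotomous tree: generation $z$ ($z = 0$ the trachea) holds $2^z$
identical branches of diameter $d(z)$ (mm, referenced at total lung
capacity, TLC). With a tracheal volumetric flow $Q$ and incompressible,
volume-conserving flow, the mean velocity in generation $z$ is

$$v(z) = \frac{Q}{A(z)}, \qquad A(z) = 2^z \, \frac{\pi d(z)^2}{4}.$$

Inhalation uses the TLC diameters directly. Exhalation diameters apply
the bronchographically measured caliber decreases, bracketed by airway
size: 13% below 1.7 mm, 16% for 1.7-3.5 mm, 10% for 3.5-7 mm and 7% at
7 mm and above. The brackets as published are ambiguous at their edges
(dashes versus strict inequalities); we close them as half-open
intervals $[1.7, 3.5)$, $[3.5, 7)$ with $\geq 7$ taking 7%, so the map
is total and single-valued — contiguity was preferred over fidelity to
the ambiguous punctuation. Because no separate functional-residual-
capacity diameter table is available, the exhalation diameter is the
single adjustment $d_{ex} = d_{TLC}(1-f)$; a global `lung_volume_scale`
is exposed for sensitivity analysis.

The embedded diameter table is the canonical Weibel "model A"
regularized 24-generation set (`weibel_diameters()`); any user table can
replace it, and outputs record which table produced them. Laminarity is
assessed with the Reynolds number $Re = \rho v d / \mu$ against the
usual $Re < 2000$ pipe-flow bound. Gas properties default to humidified
air at body temperature ($\rho = 1.12$ kg m$^{-3}$,
$\mu = 1.87\times10^{-5}$ Pa s); the laminarity margin at quiet
breathing is large, so this choice is not load-bearing. The model is
steady-flow: it deliberately ignores the shorter duration of expiration
relative to inspiration and any waveform shape.

```{r airway}
ft15 <- flow_table(build_weibel_tree(), flow_lpm = 15)
max(ft15$re_inhale, ft15$re_exhale)   # maximum Re at quiet breathing
all(ft15$laminar)
```

At 15 L/min (quiet breathing) the maximum Reynolds number in the tree is
about 1139, at the trachea during exhalation — laminar throughout. At
75 L/min (moderate exercise) proximal generations exceed 2000 and the
laminar model is outside its regime there; it is retained as stated.

### The deep-asymmetry question

How deep does an expiratory-minus-inspiratory velocity excess of more
than 1 m/s reach at 75 L/min? The published analysis states generation
10. With the canonical model A diameters and the bracketed narrowing
rules, this package computes:

```{r asymmetry}
ft75 <- flow_table(build_weibel_tree(), flow_lpm = 75)
round(ft75[1:12, c("generation", "v_inhale", "v_exhale", "delta_v")], 3)
deepest_asymmetric_generation(ft75, threshold = 1)
```

`delta_v` reaches 1 m/s only in scattered mid-proximal generations
(3, 4, 6 here), never as a contiguous run from the trachea, so
`deepest_asymmetric_generation()` returns `NA`. The *exhalation
velocity itself* stays above 1 m/s down to generation 10, which may be
what the published claim tracks. The source velocity table was not
available to reconcile the two, so we report both side by side and do
not force agreement.

## 2. Bead-track kinematics

In vitro, 1 um fluorescent beads embedded in the mucus layer of an
airway culture are imaged at 100 fps through a 15 s protocol: 5 s of no
flow, a 5 s unidirectional air pulse (1 m/s mimics resting expiratory
velocities in proximal generations; 5 m/s exercise), and 5 s of
recovery. The analysis chain is:

1. **Completeness filter.** Beads that cannot be followed from the
   pre-pulse phase to the end of recovery (out of focus, out of field)
   are excluded; the tolerance is one frame interval at either end (the
   upstream tracker defines truncation; no slack rule is published, so
   one frame is the natural choice at a declared frame rate).
2. **Ciliary drift.** Residual ciliary beating is estimated from the
   no-flow window as one constant velocity vector per field: per track,
   endpoint displacement over elapsed time, averaged over the 10-20
   beads of a field. A warning is raised outside that field size.
   Whether drift was estimated per field or pooled across cultures is
   not documented upstream; per-field is implemented (a per-track
   option exists through `pulse_metrics(drift = ...)`).
3. **Signed projected metrics.** Drift-corrected positions are projected
   onto the declared airflow axis; positions at the protocol times are
   taken from the nearest frame (at 100 fps the timing error is at most
   5 ms — interpolation was rejected as needless). Then
   `pulse = p(t_{pulse,end}) - p(t_{pulse,start})`,
   `recoil = p(t_{end}) - p(t_{pulse,end})` (opposite in sign for a
   recoiling layer), `net = pulse + recoil` exactly, and
   `percent_recovery = |recoil|/|pulse| \times 100`. Metrics are signed
   projections rather than Euclidean path lengths because transport and
   recoil happen along the airflow direction; recovery is defined as 0
   when the pulse displacement is below a configurable noise floor
   (default 0.05 um) to avoid noise-dominated ratios.
4. **Ensemble.** Mean, SD and n per metric; excluded tracks contribute
   to nothing. Means (not medians) are used, matching mean ± SD
   reporting conventions.

## 3. Radiotracer clearance

In vivo, ~150 nL of Tc-99m sulfur colloid is deposited in the airway and
imaged by gamma camera (~3000 photopeak counts at baseline). The
analysis:

* **Coregistration.** Subdermal fiducial point sources record animal
  movement; the per-frame rigid translation is the fiducial-centroid
  shift relative to frame 1 (markers are few and well separated, so
  ordering is stable and no matching algorithm is needed).
* **Percent cleared.** $100\,(1 - N(t)/N(0))$. Radioactive-decay
  correction (half-life 6.01 h) is implemented but off by default — over
  a 15 min study it is a sub-3% effect. A constant background term is
  available, default 0.
* **Initial rate.** OLS slope of percent cleared versus time over the
  0-5 min window, in %/min. The published rate definition (slope versus
  endpoint difference) is not stated; the slope is the default because
  it is robust to frame-timing jitter, and the endpoint variant is
  exposed as an option.
* **Biphasic fit.** The standard two-compartment radioaerosol model
  $$pc(t) = 100\left[F(1-e^{-k_f t}) + (1-F)(1-e^{-k_s t})\right]$$
  is fitted by bounded Levenberg-Marquardt least squares from an
  18-point starting grid ($F \in \{0.3, 0.6, 0.9\}$, fast rates scaled
  to the observation span, two slow/fast ratios); parameters are
  reordered so $k_f \ge k_s$, and fits collapsing to a single
  exponential ($F$ within 1% of 0 or 1, or $k_f$ within 5% of $k_s$)
  are flagged degenerate rather than silently accepted.
  Non-convergence from every start is an error with diagnostics.
* **Frequency regression.** OLS of initial rate on breathing frequency
  (breaths/min), returning slope (%/min/bpm), intercept and $R^2$; at
  least 3 animals and non-constant frequency required.
* **Bead recovery.** Neonatal tracheal clearance as
  $100\,( \text{injected} - \text{recovered})/\text{injected}$, with
  recovered counts above injected clamped (counting error) under a
  warning.

## 4. What the synthetic generators emulate

The generators produce data with exactly the statistical structure the
analyses assume — no more.

**Tracks** (`simulate_tracks()`): along the airflow axis each bead
follows a phenomenological kinematic model chosen for analytic ground
truth — zero displacement before the pulse; during the pulse a
saturating-exponential fast phase (amplitude 15 um, time constant
0.5 s) plus linear steady creep (4 um/s), reproducing the biphasic
rapid-then-steady displacement shape; after the pulse an exponential
recoil removing a fraction (default 0.4) of the pulse displacement with
a 0.5 s time constant. Constant ciliary drift (default (0.3, -0.2)
um/s) acts throughout, and i.i.d. Gaussian localization noise (SD
0.1 um) corrupts every spot. Defaults are order-of-magnitude plausible
for normally hydrated (10 mg/mL) mucus under a 5 m/s, 5 s pulse — they
are illustrative regimes, not values fitted to any experimental traces.
The true asymptotic net displacement is
$(1-\text{recovery fraction}) \times \text{pulse displacement}$
(21.0 um at defaults); the value at the last recorded frame is stored
alongside, since a finite recovery window leaves the recoil marginally
incomplete. This is not a rheological model: it makes no claim about
moduli, shear-thinning, or adhesion, and passing recovery tests says
nothing about those aspects of real mucus.

**Clearance** (`simulate_clearance()`): retained fraction
$r(t) = F e^{-k_f t} + (1-F) e^{-k_s t}$ (defaults $F = 0.6$,
$k_f = 0.25$/min, $k_s = 0.01$/min — an initial rate of 8.8 %/min, in
the mid range of reported in vivo rates), counts Poisson with mean
$3000\,r(t)$ (Poisson being the physically standard model for
scintigraphy counting noise), frames every 30 s for 15 min, and three
fiducials displaced by i.i.d. per-frame rigid shifts (SD 0.5) plus
localization jitter (SD 0.1). The recorded true initial rate is the OLS
slope of the noiseless $100(1-r(t))$ over the in-window frame times —
i.e. the estimand of `initial_rate()` itself.

**Frequency cohort** (`simulate_frequency_cohort()`): frequencies
uniform over 60-130 bpm (spanning isoflurane through ketamine/xylazine
anesthesia regimes), rates linear in frequency (slope 0.08 %/min/bpm)
plus Gaussian noise with SD 0.65 %/min, which places the expected $R^2$
near 0.86 — the strength of correlation the in vivo cilia-ablated data
show; the $R^2$ itself is never asserted, only slope recovery.

What the generators do *not* emulate: bead loss and refocusing events
(incomplete tracks must be appended explicitly), spatially varying or
time-varying drift, detector dead time or scatter, ROI redefinition, and
any coupling of clearance rate to mucus properties.

## 5. Numerical choices and degenerate inputs

* Units are SI internally (m, s, m$^3$/s); mm, um and L/min appear only
  at interfaces.
* Seeds: every generator takes an explicit `seed` and restores the
  caller's RNG state, so identical parameters and seed are
  byte-reproducible; the command-line layer records the seed in a
  timestamp-free manifest with MD5 hashes of inputs.
* Degenerate cases: zero flow gives all-zero velocities and Reynolds
  numbers; a motionless bead reports zero metrics and 0% recovery (not
  0/0); constant counts give an all-zero clearance curve; a zero
  baseline, a constant breathing frequency, a collapsed bpm range, or
  fewer than 2 in-window frames are errors, not silent defaults.
* Problem sizes in the test suite — 40-100 seeded replicates for the
  Monte-Carlo recovery checks, 15-bead fields at 100 fps, 31-frame
  count series — were chosen as the smallest sizes at which the
  standard-error bounds being asserted are meaningful.

## 6. Known limitations

The airflow model is steady, symmetric and laminar: no expiratory/
inspiratory duty-cycle weighting (a sinusoidal weighting was considered
and left out of the core as the published model is steady), no
turbulence in proximal generations at exercise flows, no pressure-drop
network, and no intra-generation velocity profile. The track analysis
assumes drift is constant per field over 15 s and that incomplete
tracks arrive already truncated. The clearance analysis assumes a fixed
ROI following rigid animal motion and stable fiducial ordering. None of
the in vitro/in vivo headline effect sizes (group differences between
ciliated and cilia-deficient animals, fold changes between velocities)
are reproducible from a desk — the synthetic regimes are motivated by
those numbers but parameter-recovery tests validate only the estimators.
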