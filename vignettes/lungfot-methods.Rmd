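---
title: "Models and methods behind lungfot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lungfot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lungfot` is a self-contained pipeline for studying how forced-oscillation
lung mechanics track the severity of acute lung-allograft rejection. Because
no raw animal data are available for this problem, the package pairs every
analysis step with a synthetic-data generator calibrated to the published
group-level values, so the whole chain — forcing design, impedance
estimation, index extraction, histomorphometry, statistics — can be exercised
and validated end to end. This vignette explains the models, the parameters
that matter, and the design decisions taken where the methodology was open.

## The forced-oscillation measurement

During an 8-s pause of regular ventilation, a small multi-sine volume
oscillation is applied at the airway opening and lung input impedance is
estimated as the pressure/flow transfer function,

$$Z_L(f) = \frac{P(f)}{Q(f)} = R_L(f) + j X_L(f),
\qquad E_L(f) = -\omega X_L(f), \quad \omega = 2\pi f .$$

The forcing contains 19 sinusoids between 0.5 and 19.625 Hz. Every component
frequency is an integer multiple $k \cdot 0.125$ Hz of the window's frequency
resolution, so each component falls exactly on a DFT bin of the 8-s window
(no spectral leakage), and no multiplier is an integer multiple of another
("mutually prime" components), so low-order harmonic distortion products of
one component cannot contaminate another component's bin.

The instrument's exact frequency list is not published. `build_protocol()`
therefore selects multipliers deterministically: it force-includes
$k \in \{4, 6, 157\}$ (0.5 and 0.75 Hz appear in the published results,
19.625 Hz is the stated maximum) and then scans $k$ upward, accepting a
candidate only if it is neither a multiple nor a divisor of any accepted
multiplier. We read "mutually prime" as pairwise non-harmonic rather than
pairwise-coprime because the published set contains both 0.5 Hz ($k=4$) and
0.75 Hz ($k=6$), which are not coprime. Phases default to Schroeder phases
$\varphi_i = -\pi i(i-1)/n$, which bound the crest factor; amplitudes are
equal per component and rescaled so the peak-to-peak volume equals the tidal
volume (0.9 mL for a 300 g rat at 3 mL/kg). The sampling rate (256 Hz) gives
an integer number of samples per window and a comfortable margin above the
Nyquist requirement; the device's true rate is not published and does not
affect bin-aligned estimation.

### Impedance estimation

The default estimator is the exact-bin DFT over the full window:
$\hat Z(f_k) = P(f_k)/Q(f_k)$. For a linear time-invariant lung and
bin-aligned forcing this is unbiased and exact, which the test suite checks
against the closed-form model impedance to a relative error below $10^{-6}$.
A Welch-style estimator ($\hat Z = S_{qp}/S_{qq}$ with per-bin coherence
$\gamma^2 = |S_{qp}|^2 / (S_{qq} S_{pp})$) is provided for imported records
longer than one window. Its segments are full protocol windows with 50%
overlap: shorter sub-windows would destroy bin alignment (adjacent components
sit 0.125 Hz apart, below the resolution of any sub-window), and a single
window yields one segment, for which coherence is degenerate. Records of at
least two windows are therefore required for the Welch path; bins whose
coherence falls below 0.9 are flagged, never dropped.

## The forward model: heterogeneous constant-phase lung

The published study deliberately avoided model fitting and read its indices
directly off the measured spectra. For the synthetic generator, however, a
physical forward model is required. We use the standard low-frequency
description of lung tissue, the constant-phase element, in parallel
compartments behind a common central airway:

$$Z_i(f) = R_{aw,i} + j\omega I_{aw,i} + \frac{G_i - jH_i}{\omega^{\alpha_i}},
\qquad \alpha_i = \frac{2}{\pi} \arctan(H_i/G_i),$$

$$Z_L(f) = R_c + j \omega I_c + \Big[ \sum_{\text{open } i} Z_i(f)^{-1}
\Big]^{-1}.$$

$G$ (tissue damping) and $H$ (tissue elastance) are in cmH2O/mL; their ratio
$\eta = G/H$ is the hysteresivity. A compartment participates only when PEEP
is at or above its closing pressure $P_{c,i}$ — a static threshold
recruitment model. The two 30-cmH2O recruitment maneuvers performed before
each measurement are modelled as resetting any history, so no hysteresis is
represented.

Each simulated animal's pressure trace is constructed in the frequency domain
($P(f_k) = Z_L(f_k) Q(f_k)$ at the protocol bins, inverse transformed), which
is exact for this linear model, and white Gaussian noise is added to pressure
at 40 dB SNR by default (the device noise floor is unknown; 40 dB leaves the
derived indices within a percent of their noiseless values).

### Scalar indices

From the estimated spectra the package derives the four indices used to stage
rejection:

* `E_low` = $E_L$(0.5 Hz) — tissue stiffness plus derecruitment;
* `E_max` = $\max_k |E_L(f_k)|$ (absolute value, because inertance can drive
  $E_L$ negative at high frequency);
* `E_het` = `E_max − E_low` — frequency dependence of elastance, an index of
  mechanical heterogeneity;
* `R_high` — resistance averaged over the top `n_high` frequencies (default
  1, i.e. $R_L$ at 19.625 Hz), dominated by airway resistance. The published
  wording ("highest frequencies") does not pin down how many frequencies were
  averaged, so `n_high` is a configuration knob.

## Grade presets and their calibration

The generator ships one preset per grade (A0 native, A0 isograft, A1, A2,
A3) in `inst/extdata/grade_presets.yaml`. Each preset gives lung-level $H$
at full recruitment, hysteresivity $\eta$ with a per-compartment dispersion,
per-compartment airway resistance, a closing-pressure distribution, and the
tissue-fraction distribution. The calibration logic, in order of what drives
what:

* $H$ sets `E_low` through $E_L(0.5\,\mathrm{Hz}) \approx H
  \omega^{1-\alpha}$;
* the closing-pressure distribution sets the PEEP dependence: the open
  fraction at PEEP $p$ is the normal CDF $\Phi((p-\mu_{Pc})/\sigma_{Pc})$,
  and elastance scales inversely with the open fraction;
* $\eta$ sets both the low-frequency resistance ($G/\omega^\alpha$ adds to
  $R_L(0.5)$) and the intrinsic frequency dependence of $E_L$ (exponent
  $1-\alpha$), hence the homogeneous part of `E_het`;
* per-compartment dispersion of $\eta$ (and of $H$, $R_{aw}$) creates
  parallel heterogeneity, the pathological part of `E_het`;
* the central inertance $I_c = 3\times10^{-4}$ cmH2O·s²/mL makes $E_L$ roll
  over below 10 Hz in the milder grades, as the published spectra show.

A first pass of these constants came from the closed forms above, followed by
a coarse numeric refinement against cohort medians of the published group
values (A1/A2 `E_low` at PEEP 0 and 4, `R_high` and `E_het` at PEEP 0, the
threefold A2:A1 elastance ratio at PEEP 4). Healthy (A0) lungs get
$\eta = 0.15$, the classic normal hysteresivity; rejecting grades get higher
$\eta$ and progressively larger dispersion, closing pressures and $H$. The
preset file is versioned and the monotonicity of the grade progression
($H$, $G$, heterogeneity, closing pressure, tissue fraction all
non-decreasing from A0 to A3) is enforced at load time.

Mechanics couple to histology through the animal's tissue fraction: each
animal draws a TF target from its grade's distribution, and its $G, H$ scale
as $(TF/\overline{TF}_{grade})^{\beta}$ with $\beta = 3.5$. This makes
$\log_{10} E_{low}$ locally linear in TF with slope
$\beta / (TF \ln 10)$ — numerically consistent with the slope implied by the
published group values across grades — so the cohort reproduces the
log-linear TF–elastance relation without any fitted link. The ratio is taken
to the grade mean rather than to the A0 mean so the coupling does not
double-count the grade effect already built into the presets.

## Synthetic histology and morphometry

The histology generator is a morphological cartoon, not a staining
simulation. It renders, on a 1024×1024 8-bit canvas: an alveolar wall
network (boundaries of a Voronoi tessellation of 260 random points, drawn in
a buffered frame around the canvas so the tissue field is spatially
stationary — otherwise uniformly sampled measurement regions would
systematically over- or under-cover border structure); vessel rings with
open lumina; perivascular infiltrate annuli whose number and width grow with
grade; and, for A3, a thicker wall base width standing in for septal
thickening. A bisection loop scales wall and annulus widths jointly until
the rendered tissue fraction hits the animal's target within ±0.005; the
achieved fraction is recorded as the ground truth before Gaussian blur
(σ = 1 px) and pixel noise (σ = 8 gray levels) are applied. The only
contracted properties are the tissue fraction, its region-to-region
dispersion, and the grade ordering of infiltrate burden — these are all the
downstream analysis consumes. The rendered "alveoli" (~32 µm across at the
nominal 0.5 µm/px) are smaller than real rat alveoli; enlarging them
doubles region-to-region TF dispersion and degrades per-animal recovery, so
the cartoon scale is kept deliberately.

Morphometry mirrors the published ImageJ procedure: global threshold
(Otsu by default; the IsoData intermeans threshold — ImageJ's default — and
a plain mean-gray threshold are available; Otsu and IsoData agree on these
images to within 0.01 of tissue fraction, while the mean-gray threshold is
biased whenever TF is far from one half), dark pixels are tissue, and at
least 15 square regions per animal (256 px, uniformly placed, overlap
allowed; an optional grid mode tiles the canvas deterministically) give the
per-animal TF mean and SD in percent. Region sampling at the defaults has a
standard error of roughly 1–1.5 percentage points per animal, so individual
animals recover their generator truth to about 2 points and group means to
well under 1.

## Statistics

`correlate()` wraps Pearson (optionally on $\log_{10} y$), Spearman with
average-rank ties, and simple OLS with the 95% confidence band of the mean
response; for simple regression $r^2$ equals the squared Pearson $r$, which
the tests assert to $10^{-12}$. `compare_groups()` covers the two designs
used here: a split-plot/repeated-measures two-way ANOVA (between-animal
factor grade, within-animal factor frequency or PEEP, animal as the error
stratum) with Bonferroni pairwise contrasts, and one-way ANOVA with
Tukey–Kramer contrasts for the TF group comparison. The repeated-measures
stratification matters: with the between-animal spread the presets inherit
from the published TF SDs, a naive two-way ANOVA on pooled rows buries the
grade-by-frequency interaction in between-animal variance, whereas the
within-animal stratum shows it clearly. `grade_correlation()` encodes grades
ordinally (both A0 groups as 0, then 1–3) and reports Pearson on the
$\log_{10}$ index alongside Spearman on the raw index.

## What the synthetic cohort does and does not show

The default cohort reproduces, by construction plus calibration: the grade
ordering of `E_low` and `E_het`, their PEEP dependence (derecruitment at low
PEEP for A1/A2; an A3 lung that barely recruits within 0–8 cmH2O), the
log-linear TF–`E_low` relation ($r^2 \approx 0.9$ on the default cohort),
and a grade–`E_het` Spearman correlation above 0.9. Passing tests on this
cohort validates the pipeline's correctness and the internal consistency of
the published group values — it cannot validate the biological claim on new
animals, and quantities the generator does not model (tissue nonlinearity,
hysteresis, airway-wall coupling, B-grade airway lesions, A4 lungs too stiff
to measure) are outside what any green test here demonstrates. Two
simplifications worth naming: A0 lungs never derecruit (all closing
pressures below zero), so their indices are exactly PEEP-flat, whereas real
normal lungs show a mild PEEP dependence of `E_het` through tissue
nonlinearity; and measurement noise is additive, Gaussian and
pressure-only.

## Numerical choices and problem sizes

Records are single 8-s windows at 256 Hz (2048 samples); Welch-path tests
use two-window records. The default cohort is 29 animals (6/6/4/7/6) at five
PEEP levels, matching the published design; property tests that depend on
cohort medians pool three seeds because the A1 group has only four animals
and single-cohort medians of so few animals are unstable under the published
between-animal TF spread. Histology unit tests render 512-px canvases for
speed; recovery and acceptance checks use the full 1024-px defaults.
Degenerate inputs fail with typed conditions: a lung with no open
compartment is "unmeasurable" (mirroring the grade too severe to measure),
a constant image has no threshold, a protocol band too narrow for the
requested component count names the constraint, and the tissue-fraction
calibration reports its last achieved fraction if it cannot converge within
50 iterations.
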