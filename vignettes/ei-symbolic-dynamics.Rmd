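---
title: "Simulating E-I ratio perturbation and its symbolic-dynamics readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating E-I ratio perturbation and its symbolic-dynamics readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science and the numerical choices behind
`eidyn`: the neural-mass network model, the ordinal symbolic-dynamics
measures, the synthetic connectome, and the statistical machinery, together
with the conventions that an implementer must fix but that are easy to get
silently wrong.

## The neural-mass network

Each of the $N = 78$ cortical regions is a lumped two-population model of
the classical alpha-rhythm type. The excitatory population's membrane
potential $V_e$ is the difference of an excitatory and an inhibitory
postsynaptic contribution; the inhibitory interneuron population's
potential $V_i$ is driven by the local excitatory rate. Postsynaptic
responses are biexponential kernels $h(\tau) = A[e^{-a\tau} - e^{-b\tau}]$
($\tau \ge 0$; zero for negative lags), and potentials convert to
population pulse densities through the two-branch exponential sigmoid
$S[V_m - V_d]$, which is continuous at threshold (value $g$) and bounded in
$(0, 2g)$.

Within a mass, the excitatory-to-inhibitory gain is $C_1 = 32$ and the
inhibitory-to-excitatory gain $C_2 = 3$. Between masses, coupling is
reciprocal and excitatory: region $k$ receives
$S \sum_j w_{kj} E_j(t - T)$ — the neighbours' excitatory pulse densities,
delayed by $T$ and scaled by the global gain $S$ and the structural weight
— through the same EPSP kernel as the extrinsic input. The extrinsic
("thalamic") drive is a pulse density $P + \sigma\,\eta_t$ with
$P = 480$ spikes/s and i.i.d. standard Gaussian $\eta_t$ per region and
step scaled by $\sigma = 1$. Gaussian noise is a modelling choice (only
"random fluctuations" around $P$ is specified by the tradition this model
follows); it is isolated in one place in `simulate_network()` so it can be
swapped.

Default parameters (`nm_params()`): $dt = 0.002$ s, EPSP $A_e = 1.6$ mV
with rates $a_e = 55$, $b_e = 605$ s$^{-1}$; IPSP $A_i = 32$ mV with
$a_i = 27.5$, $b_i = 55$ s$^{-1}$; sigmoid $g = 25$ s$^{-1}$,
$q = 0.34$ mV$^{-1}$; thresholds $V_{d1} = V_{d2} = 7$ mV; delay
$T = dt$. The two swept parameters are $V_{d2}$ (6–8 mV in steps of 0.5;
raising it makes interneurons harder to recruit, weakening inhibition and
raising the E–I ratio $E/(E+I)$) and the coupling gain $S$ (0–2 in steps of
0.5).

**Integration.** Each kernel is realized exactly as its equivalent
second-order linear filter ($\ddot y = A(b-a)u - (a+b)\dot y - ab\,y$,
which has impulse response $h$), advanced with fixed-step explicit Euler at
$dt$. At $dt = 0.002$ s the fastest rate ($b_e = 605$ s$^{-1}$) gives
$dt\,\lambda \approx -1.2$, well inside the Euler stability region. All
states start at zero and the first `burn_in = 1000` samples (2 s) are
discarded; the decoupled deterministic system is at its fixed point to
$10^{-6}$ mV well within that window. A non-finite state aborts with the
step and region named. Given (parameters, connectome, seed) the output is
bitwise reproducible.

With these settings the balanced network produces noise-driven, weakly
damped oscillations with a spectral peak near 8–10 Hz — the resting-state
alpha regime the model was built for. The E–I ratio is computed per region
from time-averaged rates as $E/(E+I)$ and averaged over regions; for
sweep-level figures, rates can additionally be min–max normalized across
the whole sweep (`ei_ratio_table()`, which records the normalization
constants as attributes). We use the raw ratio for monotonicity statements:
past the synchronization transition the growing network oscillation
inflates the *mean* inhibitory rate through the convex lower branch of the
sigmoid (a Jensen effect), which makes the normalized inhibitory rate — and
with it the normalized ratio — mildly non-monotone in $V_{d2}$ even though
the raw ratio increases strictly. For the same reason the "higher
$V_{d2}$ ⇒ lower mean inhibitory rate" ordering is a statement about the
mass-level mechanism and is tested in the weak-coupling regime, where it
holds strictly.

## The synthetic connectome

The empirical average DTI connectome used in the original study is an
external download, so the package ships a generator that emulates its
essential features: `synthetic_connectome()` draws a symmetric,
zero-diagonal, connected weighted graph in which edge $(i, j)$ is included
with probability proportional to $i^{-\gamma/2} j^{-\gamma/2}$
(`hub_exponent` $\gamma = 2$ by default), giving a heavy-tailed degree
distribution with clear hubs (max/min nodal strength well above 3:1 at the
default 15% edge density). Edge weights are uniform on $(0.5, 1.5)$ and the
matrix is rescaled to a mean nodal strength of 8.

The strength scale is the one genuinely free constant, and it was fixed
once, by the study's own design condition: the balanced model
($V_{d2} = 7$, $S = 1$) is meant to sit close to the network's phase
transition between asynchrony and synchrony. An amplitude scan across
strengths showed the synchronization onset crossing the
$V_{d2} \in [6.5, 7.0]$ interval at $S = 1$ for mean strength 8; weaker
scales push the transition above $V_{d2} = 8$, stronger scales below 6.5.
With this placement the low-E-I model (6.5) is subcritical (high signal
variability, low coupling) and the high-E-I model (7.5) supercritical, which
is the configuration all regional analyses assume.

What the generator does *not* emulate: spatial embedding and distance-
dependent connection probability, hemispheric symmetry, the empirical
weight distribution of tractography counts, and the specific hub identity
of the human cortex. Tests passing on this graph therefore demonstrate the
mechanism — hub-selective degree loss under reduced E-I ratio, directional
relationships between the measures and $V_{d2}$ — not anatomical
specificity; quantitative regression coefficients will differ on the
empirical matrix. File IO uses plain delimited text (optional header row,
sidecar label file); asymmetries beyond $10^{-9}$ are an error rather than
silently symmetrized, because the model's coupling is defined as
reciprocal.

## Ordinal symbolization and the three measures

Windows of $n = 4$ samples spaced $\tau$ apart are encoded by the ordinal
pattern of their amplitudes; $4! = 24$ patterns exist and a series of
length $L$ yields $L - (n-1)\tau$ symbols. Three conventions are fixed and
deliberately explicit:

* **ties** are broken by temporal order (the earlier sample ranks lower) —
  the classic convention; relevant only for quantized data;
* **pattern indexing** is the lexicographic rank of the argsort
  permutation (computed via the Lehmer code); any consistent bijection
  would do, but this one is stated so symbol streams are comparable across
  tools;
* **logarithms** are natural, with explicit normalization constants, so
  all results are base-independent; $0 \log 0 := 0$ everywhere.

With $n = 4$ and the study's 4096-sample epochs, $n! = 24 \ll 4096$, the
regime where pattern probabilities are estimable; `symbolize()` warns when
a series is shorter than $10\,n!$.

**PE** is the Shannon entropy of a region's pattern distribution divided by
$\log n!$, so it lies in $[0, 1]$.

**wsMI** follows the weighted symbolic mutual information convention of the
EEG literature: $\mathrm{wsMI} = \frac{1}{\log n!} \sum_{x,y} w(x,y)\,
p(x,y) \log \frac{p(x,y)}{p(x)p(y)}$ with $w = 0$ for identical pattern
pairs and for sign-opposite pairs (the pattern the amplitude-inverted
window would produce, i.e. rank reversal; time reversal is *not* masked),
and $w = 1$ otherwise. This is the volume-conduction correction: a common
source mixed instantaneously into two signals produces identical or
inverted patterns, which carry zero weight, so a signal has exactly zero
wsMI with itself and with its sign-inverse. In a simulation volume
conduction does not exist, but the correction is retained so results are
comparable with empirical pipelines; it is exposed as `vc_correction` so
the uncorrected variant is testable.

**JPE_inv** is $1 - H(p_{XY}^{\mathrm{masked}})/\log M$, where the joint
pattern distribution is masked by the same weight matrix and renormalized,
and $M = n!^2 - 2\,n!$ (= 528 for $n = 4$) is the number of admissible
joint states — rank reversal has no fixed points, so exactly $2\,n!$ cells
are masked and the measure lies in $[0, 1]$: 0 for independent streams
(joint entropy maximal), higher for coupled ones. Masking both measures
keeps wsMI and JPE_inv comparisons on the same co-occurrence support. Two
identical symbol streams have no admissible joint states after masking;
that degenerate case is an error by design rather than a silent 1.

Both pairwise measures are estimated from empirical cell frequencies
without bias correction; at 4093 symbols the wsMI null bias is
$\approx (M-1)/(2L\log n!) \approx 0.02$, which is visible in the sweep
tables but irrelevant to the contrasts and correlations the study uses.

**Filtering.** The pass-bands (0.5–70 Hz broadband, 6–13 Hz extended
alpha) are applied zero-phase before symbolization — ordinal patterns are
sensitive to phase distortion — as a 4th-order Butterworth run forward and
backward (`signal::filtfilt`). A linear-phase FIR design was considered and
rejected: a 0.5 Hz edge at $f_s = 500$ Hz needs several thousand taps,
comparable to the 4096-sample epochs themselves. The forward–backward
Butterworth gives an effectively 8th-order magnitude response (a 2 Hz tone
through the alpha band is attenuated by ~5 orders of magnitude) with no
phase cost. The delay $\tau$ is applied after filtering. The three default
conditions are (0.5–70 Hz, $\tau = 1$), (6–13 Hz, $\tau = 1$) and
(0.5–70 Hz, $\tau = 50$): fast/mixed, alpha-specific and slow time scales.
The condition table accepts any $(\mathrm{band}, \tau)$ list, so a
$\tau$-sweep (e.g. 1…64 on broadband, where the $V_{d2}$ relationship
stabilizes for large $\tau$) is a configuration, not a code change.

## Degree, hub disruption, statistics

Functional degree is the mean off-diagonal connectivity of a region (the
diagonal is always excluded). The hub disruption index is the OLS slope of
(perturbed − reference) degree on reference degree, with the balanced model
always on the x-axis; the fitted object carries slope, offset, $R^2$,
$F = R^2 (N-2)/(1 - R^2)$ with $df = (1, N-2)$, and the two-sided $p$.
Swapping the roles of the two models is a different regression, not a sign
flip. If the degree change is constant the slope is zero and $R^2$ is
defined as 0 (the $F$-statistic's numerator sum of squares vanishes).

Statistical design decisions, made where the design was genuinely open:

* whole-brain comparisons use one value per run as the sampling unit
  ($n = 10$ per model) and a pooled-variance Student $t$ (equal group
  sizes; Welch available behind a flag) with pooled-SD Cohen's $d$;
* correlations with $V_{d2}$ use run-level whole-brain means across the
  five $S = 1$ models ($n = 50$); a model-level variant is a one-line
  `group_by`;
* regional comparisons are Mann–Whitney U tests over runs ($n = 10$ per
  region per model), with the U statistic reported in the first-group
  orientation and exact p-values for small tie-free samples;
* multiplicity is controlled per (metric, condition, comparison) family of
  78 regions with the two-stage linear step-up FDR procedure at
  $q = 0.01$: Benjamini–Hochberg at $q' = q/(1+q)$, estimate
  $m_0 = m - r_1$, then Benjamini–Hochberg again at $q' m / m_0$. No
  installed package exposes this procedure, so it is implemented directly
  from the recipe and cross-checked in the tests against an independently
  coded second implementation.

## Orchestration, seeds and problem sizes

`run_study()` sweeps the $(V_{d2}, S)$ grid with `runs_per_model`
independent simulations per cell. Per-cell seeds come from folding the base
seed with the grid and run indices through a multiplicative congruential
hash (`cell_seed()`, kept below $2^{31}$), so any single cell can be
recomputed in isolation — a property the tests assert bitwise. Ten runs are
independent initializations, not one long recording split into epochs.

Whole-brain tables keep one row per (model, run, condition); per-region
profiles and run-averaged connectivity matrices are retained for the three
focus models (low 6.5 / balanced 7.0 / high 7.5 at $S = 1$) by default
(`keep_matrices`). The full default grid (25 models × 10 runs × 3
conditions, 78 regions) runs in roughly ten minutes on one CPU; the
acceptance-scale study used throughout the tests — the $S = 1$ column only,
at full per-model size — takes about two. The unit-test fixtures use
reduced sizes (16–20 regions, 2 runs, 512 samples), which exercise every
code path in seconds.

## Known limitations

* $V_{d2}$ is varied homogeneously; region-specific excitability maps
  (e.g. pathology-weighted) are out of scope.
* The mean inhibitory rate is non-monotone in $V_{d2}$ past the
  synchronization transition (see above); the E-I ratio itself is not.
* wsMI and JPE_inv carry a small positive finite-sample bias; comparisons
  across equal-length epochs are unaffected.
* HDI magnitudes depend on the connectome; on the synthetic graph the
  low-E-I slopes come out near $-1$, and only their sign and significance
  — not their exact values — should be read as the reproducible result.
* The model generates alpha-dominated dynamics; broadband results do not
  emulate the full spectral content of empirical recordings.
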