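---
title: "Methods: off-path folding kinetics of consecutive telomeric G-quadruplexes"
author: "telofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: off-path folding kinetics of consecutive telomeric G-quadruplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telofold)
```

## Scientific background

Human telomeric DNA carries long runs of TTAGGG repeats. A strand with
eight repeats (Tel8) can fold two G-quadruplexes (G4) side by side, but a
single G4 can nucleate at any of five internal positions. Only the two
terminal placements leave four free repeats for a second G4; the three
internal placements block it. If nucleation is kinetically equipartitioned
— every position equally likely — then right after folding starts only
40% of molecules are *on-path* to the fully folded two-G4 form, and 60%
sit in *off-path* one-G4 conformations that must unfold before full
folding can proceed. This kinetic partitioning is the package's central
model: it explains why single-molecule FRET experiments see fast initial
G4 formation but hours-slow approach to equilibrium, and why a
substantial partially folded population persists even in strongly
G4-promoting buffers.

The package provides four connected layers:

1. a **kinetic model** of the off-path mechanism with deterministic and
   stochastic solvers, closed-form equilibria and rate fitting
   (`kinetic_model()`, `simulate_ode()`, `simulate_gillespie()`,
   `equilibrium()`, `fit_rates()`);
2. **single-molecule FRET quantification**: alternating-laser-excitation
   (ALEX) corrections, frame-weighted efficiency histograms, folded
   fractions and split-sample uncertainties (`correct_trace()`,
   `build_histogram()`, `folded_fraction()`, `fraction_uncertainty()`);
3. **trace segmentation**: photobleaching-based trace selection, Gaussian
   hidden Markov modelling, dwell times and exponential lifetimes
   (`select_traces()`, `fit_hmm()`, `extract_dwells()`,
   `fit_dwell_lifetime()`, `classify_trace()`);
4. a **synthetic trace generator** reproducing the full measurement chain
   so that every analysis stage can be validated against known ground
   truth (`generator_config()`, `render_trace()`,
   `generate_timecourse_dataset()`), plus the Förster conversion used to
   compare structural ensembles with measured efficiencies
   (`distance_to_fret()`, `ensemble_efficiency()`).

## The kinetic model

States are `U` (unfolded), `P2`…`P6` (one G4 at repeat positions 2–6) and
`F` (two G4s). Transitions:

* `U -> Pi` at rate `k_f * w_i`, where `k_f` is the *total* nucleation
  rate and `w` the nucleation weights (uniform by default). Making `k_f`
  the total exit rate ties the unfolded-state dwell lifetime to `1/k_f`,
  which is how unfolded-state lifetimes are measured from traces.
* `Pi -> U` at the common rate `k_u`: all one-G4 states are assumed
  equally stable regardless of position.
* `Pi -> F` at `k_f2`, for on-path `Pi` only (default `{P2, P6}`).
* `F -> Pi` (on-path) at total rate `k_u2`, split in proportion to the
  on-path nucleation weights. Off-path states communicate with `F` only
  through `U`: internally nucleated G4s must unfold before full folding,
  which is the mechanism's defining constraint. Whether a direct
  repositioning pathway exists is left out deliberately; the tree
  topology realizes the "first needs unfolding" picture.

The two experimentally distinguished fully folded conformations (FRET
states around 0.8 and 0.6) are merged into the single kinetic state `F`:
the rate model does not resolve separate rates for them, and only the
emission map differentiates them.

Because the transition graph is a tree, the stationary law satisfies
detailed balance and has the closed form
`pi_Pi/pi_U = k_f w_i / k_u`, `pi_F/pi_U = k_f k_f2 W_on / (k_u k_u2)`
with `W_on` the total on-path weight. `equilibrium()` implements this and
is cross-checked in the tests against the numerical null space of the
generator. Degenerate configurations are rejected: `k_f = 0` or
`k_u = 0` makes the chain reducible, and `k_f2 > 0` with `k_u2 = 0` makes
`F` absorbing; `k_f2 = 0` is allowed and gives `pi_F = 0`.

`simulate_ode()` propagates `dp/dt = p Q` by the matrix exponential of
the fixed 7×7 generator, evaluated through one eigendecomposition per
model (all requested times reuse it) with a scaling-and-squaring Taylor
fallback for numerically defective generators. `simulate_gillespie()` is
the exact stochastic twin, vectorised over molecules; the two are
required to agree within binomial Monte-Carlo error in the test suite.

Two model-level facts serve as fixed points of the implementation: with
uniform weights the initial partition is exactly 40% on-path / 60%
off-path, and with `k_u = k_u2 = 0` (folding only) the long-time folded
fraction equals the on-path fraction — the kinetically trapped limit that
matches the observation that roughly a third of molecules are already
fully folded minutes after folding starts.

`delta_g()` converts a rate ratio to the folding free energy
`-RT log(k_fold/k_unfold)` in kJ/mol (R = 8.314462618 J/mol/K,
T = 298.15 K by default).

## Rate fitting and its identifiability limit

`fit_rates()` fits the folded-fraction time course (fraction of molecules
with E ≥ 0.6 versus time after the folding trigger) by weighted least
squares, weights `1/sd^2` when uncertainties are supplied. Free rates are
optimised on a log scale with a bounded multi-start local search
(Nelder-Mead plus L-BFGS-B polishing from 20 log-uniform starts by
default), because the landscape has plateaus and, as it turns out,
something stronger:

**the folded-fraction curve from an all-unfolded start does not identify
all four rates.** The observable is the `F`-occupancy of an effectively
4-state linear chain (off-path block ← U ↔ on-path block ↔ F), a sum of
three exponentials, and distinct rate sets can produce *identical*
curves — the analogue of the classical rate-swap ambiguity of
two-exponential relaxations. For example, `(k_f, k_u, k_f2, k_u2) =
(0.02, 0.005, 0.05, 0.01)` and `(0.0592, 0.0050, 0.0169, 0.0039)` s⁻¹
match to machine precision. `fit_rates()` therefore

* reports an `identifiable` flag and warns when statistically tied optima
  disagree on the parameters (ties are judged by the 95% chi-square
  increment for weighted fits, by numerical resolution otherwise);
* breaks *numerical* ties deterministically toward the solution closest
  (in log-rate distance) to the template's starting rates, so that
  self-consistency fits started at the generating rates return them;
* regains full identifiability when independently measured rates are
  pinned via `fixed` — in practice the unfolding rates `k_u`, `k_u2`
  obtained from dwell-lifetime analysis of equilibrium traces, which is
  exactly how the time-course modelling is meant to be used. The
  validation suite fits `k_f` and `k_f2` with the unfolding rates fixed
  when observation noise is present.

Profile-likelihood 95% intervals are computed per free rate by
re-optimising the remaining rates along an expanding walk and bisecting
the Δχ² = 3.84 crossing.

## FRET quantification

With ALEX three channels are recorded per 200 ms frame: `F_DD` (donor
emission, donor excitation), `F_AD` (acceptor emission, donor
excitation) and `F_AA` (acceptor emission, acceptor excitation). The
correction chain in `correct_trace()` is the standard one: per-channel
background subtraction first, then donor leakage `alpha * F_DD'` and
direct excitation `delta * F_AA'` removed from the acceptor channel, then

    E = F_AD' / (F_AD' + gamma * F_DD')

with defaults `alpha = 0.15`, `delta = 0.05`, `gamma = 1.2` (averaged
trace-derived values for this dye pair and detection path). `E` is not
clipped: corrected values legitimately leave [0, 1] under noise. Frames
with a non-positive denominator (e.g. after donor bleaching) are flagged
invalid and excluded — never imputed. Bulk (cuvette) efficiencies use the
uncorrected proximity ratio `ensemble_fret()`.

Histograms are frame-weighted (each usable frame is one count) over the
fixed range [-0.1, 1.1] with 0.025-wide bins anchored so a bin edge falls
exactly at the E = 0.6 full-folding threshold; `folded_fraction()`
refuses thresholds that would split a bin. Exclusion of invalid frames is
frame-level, not trace-level. Population uncertainties follow the
split-sample recipe: the trace pool is randomly partitioned into three
near-equal groups (remainders round-robin, deterministic given the seed),
a histogram and folded fraction computed per group, and the mean and
standard deviation across groups reported.

## Trace selection and HMM segmentation

Usable molecules are those whose fluorophores bleach in a single step.
`select_traces()` implements a reproducible proxy for this visual
criterion: recursive two-segment mean fits locate downward steps larger
than 3× the channel noise (estimated from successive differences) on the
summed donor-excitation signal `F_DD + F_AD` (donor bleaching) and on the
ALEX channel `F_AA` (acceptor bleaching). `F_AA` is used for the acceptor
because with `gamma` = 1.2 the acceptor-bleach step in the summed
donor-excitation channel has amplitude only `E (1 - 1/gamma) I` — buried
in noise — while `F_AA` carries the full acceptor brightness and is
insensitive to FRET dynamics. More than one downward step in either
channel rejects the trace (e.g. doubly-labelled molecules); traces
without any bleach are accepted at full length, and the usable range ends
at the first detected bleach.

`fit_hmm()` segments corrected traces with a Gaussian-emission hidden
Markov model fitted by Baum-Welch expectation-maximization (the
forward-backward and Viterbi kernels are compiled), with the number of
states chosen by BIC over k = 1…`max_states` and five seeded restarts per
k. This replaces the variational-Bayes evidence used by interactive
trace-analysis software with a deterministic, dependency-light criterion
that selects the same k on well-separated states; a VB backend could be
added behind the same interface. States are relabelled by ascending mean,
so all downstream quantities are invariant to label permutations.
Zero-variance traces short-circuit to a one-state result.

Dwells are maximal runs of the Viterbi path; the first and last dwell of
every trace are censored and excluded from lifetime fits. Two lifetime
estimators are provided: the maximum-likelihood mean of uncensored dwells
(default) and a binned dwell-time histogram fitted with a single
exponential by nonlinear least squares (bin width defaulting to one
frame), the classical route; the tests require the two to agree within
joint standard errors. `classify_trace()` assigns the low/high FRET
groups (high iff any visited state mean ≥ 0.6) and flags direct jumps
between the lowest (≤ 0.25) and highest (≥ 0.6) states — the rare
transitions that bypass intermediates. The 0.25/0.6 bounds quantify a
qualitative description; they are deliberately conservative.

## The synthetic generator

`render_trace()` inverts the entire analysis chain so the analysis can be
validated end to end: state paths from the exact CTMC sampler are
converted per frame to a true efficiency (the occupancy-weighted average
of state emission means over the frame — motion blur at 200 ms
integration — jittered by the emission width), then to ideal intensities
`F_AD = I·E`, `F_DD = I·(1-E)/gamma`, `F_AA = I`, then distorted by
leakage, direct excitation, backgrounds and additive Gaussian channel
noise, with independent exponential photobleaching clocks for each dye.
After acceptor bleaching the donor dequenches (E → 0); after donor
bleaching both donor-excitation channels drop to background. Ground
truth (per-frame state by majority occupancy, realized E, bleach frames)
rides along for oracle tests; with zero channel noise,
`correct_trace ∘ render_trace` is the identity on the realized E to
better than 1e-9.

Default conditions mirror the experiment: 0.2 s frames, 500 s records,
`alpha/delta/gamma` = 0.15/0.05/1.2, emission means 0.2 (U), 0.4 (one-G4
intermediates) and 0.8 (two-G4). Values the experiment does not pin down
were chosen once as plausible instrument settings and are declared, not
inferred: total intensity 1000 photons/frame, channel noise sd 30,
backgrounds 50, bleaching rate 0.002 s⁻¹ per dye (500 s mean), emission
widths 0.05 E units — wide enough to overlap neighbouring states yet
separable, matching the appearance of measured histograms. The noise
model is additive Gaussian rather than shot noise: it is analytically
invertible and suffices to exercise the correction stage; camera physics
(EM gain, blinking, drift) is out of scope. Time-course ensembles start
every molecule unfolded at t = 0, emulating the LiCl → NaCl buffer
exchange that triggers folding.

## Structural ensembles

`distance_to_fret()` applies the Förster relation
`E = 1/(1 + (d/R0)^6)` with `R0` = 52 Å; orientation effects are folded
into the fixed `R0`, as is standard when a single Förster radius is
quoted. `ensemble_efficiency()` summarises a sample of dye-dye distances
either *dynamically* (mean of per-sample efficiencies; the default, since
dye motion is fast relative to the 200 ms frame) or *statically*
(efficiency of the mean distance), with box-plot statistics (quartiles,
1.5×IQR whiskers) of the per-sample efficiencies. Both modes are exposed
because ensemble figures do not always state which convention they use.

## Validation scale and limitations

The test suite and the acceptance script regenerate everything from code:
CTMC path ensembles of 10⁴ molecules for solver equivalence, 100 random
models for the equilibrium closed form, 50 replicate 2500-frame
four-state traces for HMM recovery, 50 replicate noisy time courses for
rate recovery, and 1000-dwell samples for lifetime estimation — sizes
chosen to give decisive statistics on a single CPU.

What passing these tests does *not* show: the generator's Gaussian-noise,
conditionally independent frames are kinder than real camera data
(correlated noise, baseline drift, blinking); real traces may violate the
single-`gamma` assumption per molecule; the kinetic model deliberately
omits G-triplex/hairpin intermediates and any direct off-path ↔ on-path
repositioning; and rates are fitted per buffer condition with no
salt-dependence law. The identifiability limit of the all-free rate fit
is intrinsic to the folded-fraction observable, not a numerical artifact
— drawing four rates from one time course requires independent
information, and the package's design (the `fixed` argument) expects it.
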