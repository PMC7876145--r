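---
title: "Models and methods behind synaptodock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptodock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptodock)
```

synaptodock quantifies two complementary views of how the disordered
presynaptic protein α-synuclein (αS) engages lipid membranes: residue-level
NMR measures of binding to small unilamellar vesicles (SUVs) mimicking the
inner and outer presynaptic-membrane leaflets, and single-vesicle TIRF
measures of how αS stabilises the docking of synaptic-like vesicles on a
supported bilayer. This vignette explains the models, the estimators, the
synthetic-data generators used to validate them, and the numerical choices
made where the design was genuinely open.

## The quadratic binding isotherm

An HSQC titration reports, for every backbone amide, the intensity ratio
$I/I_0$ relative to the lipid-free spectrum. Because exchange between the
free and vesicle-bound protein broadens the bound state beyond detection,
the per-residue bound fraction is estimated as $\chi_B = 1 - I/I_0$.
With total protein concentration $P$, total lipid $S$, and one protein
occupying $L$ lipids, mass action with explicit ligand depletion gives the
physical root of a quadratic:

$$\chi_B = \frac{(P + S/L + K_D) - \sqrt{(P + S/L + K_D)^2 - 4\,P\,S/L}}{2P}.$$

`eval_binding_model()` implements this closed form; the test suite checks
it against an independent `uniroot()` solution of the underlying
equilibrium $(P - C)(S/L - C) = K_D C$ over a dense parameter grid.
Ligand depletion matters here: at 50 µM protein the strong-binding regime
($K_D$ of a few µM) is far from the dilute-ligand hyperbola, and the
stoichiometry $L$ is identified mainly by the low-concentration,
depletion-limited part of the curve.

`compute_bound_fraction()` averages $1 - I/I_0$ across the residues of a
region (N-terminal anchor, residues 1–25, or the central segment 65–97
that overlaps the NAC region) at each lipid concentration; the fit is then
performed on the region-averaged curve, matching how such binding curves
are reported, rather than fitting per residue and averaging the constants.
Negative per-residue attenuations caused by noise are retained so the
region mean stays unbiased near zero binding.

`fit_binding_curve()` minimises weighted least squares in $(K_D, L)$ with
`minpack.lm::nlsLM`. Points are weighted $1/\mathrm{sd}^2$ when every
point has a positive across-residue standard deviation, uniformly
otherwise (a noiseless curve has zero spread). Because the surface has
long shallow valleys in the weak-binding regime, the fit is multistarted:
$K_D$ from the half-saturation concentration of the curve scaled by
$\{0.1, 1, 10\}$ and $L \in \{1, 5, 10, 20, 50\}$, inside box bounds
$K_D \in (10^{-3}, 10^6)$ µM and $L \in (0.1, 10^3)$. Non-convergence is
reported via a flag, not an exception, so a curve with no signal (all
$\chi_B \le 0.05$) degrades gracefully.

## CEST profiles and the detached-population estimator

Chemical exchange saturation transfer saturates the invisible
membrane-bound state with a weak field at a series of offsets
(±1.5 … ±28 kHz, with a −100 kHz reference); exchange carries the
saturation into the visible free state, so the residue-level ratio
$I/I_0$ drops where the residue is membrane-attached. Profiles of broad
bound states are symmetric in the offset, and `average_cest_offsets()`
averages the ±x pair to halve the noise.

The synthetic generator is deliberately phenomenological, not a
Bloch–McConnell simulation: the noiseless ratio is

$$I/I_0(\Omega) = \left[1 - p_b\,\frac{w^2}{w^2+\Omega^2}\right]
 \left[1 - \frac{d^2}{d^2+\Omega^2}\right],$$

a Lorentzian transfer efficiency of half-width $w$ (default 10 kHz —
bound-state resonances are tens of kHz broad, so transfer is nearly
complete at ±1.5 kHz) times a direct-saturation factor of half-width $d$
(default 0.35 kHz, the order of the 350 Hz saturation bandwidth). The
downstream estimators only consume profile shapes, which this reproduces;
exchange-rate physics is out of scope.

The population of conformations in which a region is *detached* from the
membrane is estimated by `estimate_detached_population()` as the ratio of
the region's mean offset-averaged ratio to that of a reference region
assumed fully detached (default the C-terminal residues 120–140, which
show no membrane affinity), clipped to [0, 1]. The estimator errors when
the reference itself is saturated (mean ratio ≤ 0.1), where the ratio is
meaningless. How the published detached populations were computed is not
stated in the experimental literature this mirrors; this ratio estimator
is the package's own definition, and it is validated only against the
package's generator, where it recovers $1 - p_b$ within ±5 percentage
points at 2% ratio noise.

Transverse relaxation decays are fit per residue by
`fit_t2()` as $A e^{-\tau_d/T_2}$; residues with no measurable decay
(constant intensity, or standard error overwhelming the estimate) are
flagged invalid rather than reported.

## TIRF image analysis

The detection chain follows standard single-particle practice for docked
(near-stationary) vesicles:

1. **Rolling-ball background subtraction** (`subtract_background()`):
   the background is the grayscale opening with a ball-shaped structuring
   element (height profile in intensity units equal to the sphere of the
   given radius, the classical rolling-ball equivalence; at radii of 1–2
   pixels the ball is nearly flat, and the exact ImageJ paraboloid variant
   is not reproduced). Opening removes structures narrower than the
   element, so subtracting it keeps sharp in-focus spots while removing
   the smooth background and the broad blobs of out-of-focus vesicles.
   The default radius is 2 px: on synthetic benchmarks it retains
   measurably more of the ~5-px spots than 1.5 px (recall 0.975 vs 0.92
   at matched precision) while still attenuating σ ≥ 6 px blobs below
   20% of their amplitude.
2. **LoG detection** (`detect_spots()`): scale-normalised
   Laplacian-of-Gaussian response at σ = diameter/(2√2) (≈1.77 px for the
   5-px spot diameter), computed separably with replicate-padded 1-D
   kernels; detections are local maxima of the negated response above a
   quality threshold, with non-maximum suppression within half the spot
   diameter and sub-pixel refinement by 1-D quadratic interpolation.
   Quality units are LoG-response counts and are not transferable from
   other software's internal units; the default threshold of 10 was
   calibrated on synthetic benchmarks to give recall ≥ 0.95 at precision
   ≥ 0.97 for spots at the default signal-to-noise, and is exposed as a
   parameter.
3. **Greedy nearest-neighbour linking** (`link_particles()`): closest
   candidate pairs first, each detection used once, links only within
   `max_displacement` (default 2 px — docked vesicles move by
   localisation jitter only). Tracks may bridge up to `max_gap` missing
   frames (default 1), with bridged frames interpolated and marked
   unobserved so a single-frame detection dropout does not split a
   residence event. This is simpler than global LAP assignment; for
   well-separated stationary spots the greedy solution coincides with the
   optimal one, which the fixtures verify.

Coordinates are 0-based with pixel centers at integer positions; frames
are 0-based throughout.

## Docking statistics

`count_docked()` counts tracks present per frame over an analysis window
(by default the last 3500 frames of a 7500-frame movie, past the initial
photobleaching transient).

`compute_acf()` implements the particle-persistence autocorrelation

$$P(\tau) = \sum_{t} \frac{1}{N_t} \sum_{i=1}^{N_t}
  \delta\!\left[w_i(t),\, w_i(t+\tau)\right],$$

where $\delta = 1$ when particle $i$ is present at both $t$ and
$t + \tau$ (identity via track id, presence including bridged frames) and
$N_t$ is the number present at $t$. Two conventions are pinned down
explicitly because the summation is ambiguous as usually written: frames
are indexed $0 \dots T-1$ and the outer sum runs $t = 0 \dots T-1-\tau$
($T-\tau$ terms); and frames with $N_t = 0$ contribute 0, keeping the
statistic a pure sum. The implementation reduces each track to presence
intervals and accumulates interval overlaps with difference arrays, and
is tested for exact equality against a brute-force triple-loop
enumeration on every fixture up to 10 frames × 5 particles. The lag grid
is every integer frame up to `tau_max` (default min(100, window/4)).

`fit_residence()` fits the P(0)-normalised curve with
$a_1 e^{-\tau/t_1} + a_2 e^{-\tau/t_2} + c_0$ under $a_1, a_2, c_0 \ge 0$,
multistarted on a grid of time-constant pairs around the curve's 1/e
crossing; the label-swap symmetry is broken by ordering $t_1 \le t_2$
after convergence. The fast constant $t_1$ absorbs short-range
decorrelation from stochastic detection loss; the slow constant $t_2$ is
the residence time, reported in ms. When the two-component model is
unidentifiable (relative standard error of $t_2$ above 100%, or an
amplitude below $10^{-3}$) the curve is refit with a single exponential
and flagged degenerate — the common case for clean simulated track sets,
whose ACF is a single geometric decay.

## The TIRF generator and what it does (not) emulate

`generate_tirf_movie()` renders Poisson docking arrivals (uniform
positions) with geometric residence durations — the discrete analogue of
an exponential residence, chosen so frame-level ground truth is exact
because the ACF is computed on frames. Docked spots are 2-D Gaussians
(σ = 1.7 px, peak 150 counts over a 100-count background by default,
chosen as realistic counts for a 4×4-binned sCMOS field; the experimental
papers this emulates do not state intensities) with per-spot exponential
photobleaching (default 0.001/frame); out-of-focus bulk vesicles are
broad (4× PSF), dim (≤ 25% of spot amplitude), mobile Gaussians whose
parameters are set so that the background-subtraction step — not luck —
removes them; pixels carry Poisson shot noise plus 2-count Gaussian read
noise. Field-level photobleaching is not simulated: the experimental
protocol bleaches pre-docked material before sampling and analyses only
the steady-state window, which the window convention already encodes.

A note on the two levels of simulation. `simulate_track_set()` generates
the same event process directly as tracks: each docking event is one
track whose identity persists for its whole residence; per-frame
detection dropout removes frames; single-frame gaps (up to `max_gap`) are
bridged, and longer dropout runs leave the track temporarily absent
without changing its identity. This emulates an idealised tracker with
perfect re-identification, which is the right reference for validating
the ACF estimator: the persistence statistic is defined on particle
identity, and for stationary docked vesicles re-identification by
position is near-perfect in practice. The image-level pipeline, by
contrast, must split a track when a dropout run exceeds its gap-closing
span; at the default signal-to-noise such runs are rare and the
image-level residence estimate lands within ~5% of truth, but with
heavy dropout the split rate adds to the apparent off-rate — a known
limitation of frame-to-frame linking, not of the ACF.

With geometric durations of mean $m$ frames the exact per-lag persistence
decay is $q^\tau$ with $q = 1 - 1/m$, so the fitted exponential constant
is $-1/\ln q$ frames rather than $m$: 880 ms for a 900 ms mean and 420 ms
for 440 ms at 40 ms frames. This ~2–5% discretisation offset is inherent
to frame-level simulation and well inside the ~10% seed-to-seed spread of
the estimator.

Problem sizes used in the validation suite were chosen to keep each check
statistically meaningful at desk scale: 2000-frame track sets with 0.5
arrivals/frame (~1000 events) for residence recovery, 20 seeds per
condition with the median compared at 10%; a single full 7500-frame,
128×128 px movie for the occupancy pipeline, compared within three
standard errors with the effective sample size discounted by the
~22.5-frame occupancy correlation time; 100 seeds for noisy $K_D$
recovery.

## Group comparisons

`welch_ttest()` implements the unpaired two-tailed t-test with Welch's
variance correction and Welch–Satterthwaite fractional degrees of
freedom, written out from the formulas so that zero-variance degenerate
inputs have defined behaviour (equal means: t = 0, p = 1; unequal: p = 0
with a flag); it is cross-checked against `stats::t.test` to 10
significant digits on random inputs. Replicate aggregation uses the
sample (n−1) standard deviation, the convention for triplicate error
bars. p-values are reported to 3 significant figures, without
multiple-testing correction, matching pairwise experimental reporting.

## Known limitations

- The CEST generator is a shape model; exchange rates, saturation power
  dependence and Bloch–McConnell physics are out of scope, so agreement
  of the detached-population estimator with its generator does not
  validate it against real saturation physics.
- The quality threshold of the LoG detector is in package-specific
  response units; thresholds from other software do not transfer.
- The linker handles near-stationary particles; diffusing particles
  at high density would need global assignment.
- Lipid concentrations are µM total lipid throughout; mass-per-volume
  inputs must be converted by the caller (no molar-mass table is
  shipped).
- Synthetic movies use uniform event positions; clustered docking sites
  would raise the merge rate of nearby spots and lower detection recall
  below the benchmarked values.
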