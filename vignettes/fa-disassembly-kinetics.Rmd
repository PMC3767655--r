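---
title: "Predicting focal adhesion disassembly from FRAP exchange kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting focal adhesion disassembly from FRAP exchange kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadyn)
```

## The question

Focal adhesions (FAs) are integrin-based multiprotein plaques that couple the
extracellular matrix to actomyosin stress fibers. When contractility is
relaxed — for instance with the ROCK inhibitor Y-27632 — FAs disassemble,
and different plaque proteins (zyxin, VASP, talin, paxillin, ILK, FAK,
vinculin, kindlin-2, ...) leave at characteristically different rates: a
fast group with decay time constants around 7–8 min, an intermediate group
near 16 min, and a slow group at 25–28 min, with adhesions near the cell
center dissociating 1.3–2 times faster than peripheral ones.

`fadyn` implements the quantitative machinery needed to test a mechanistic
explanation: that the drug shifts each protein's molecular exchange rates at
the adhesion — its apparent association rate $k_{on}$ and dissociation rate
$k_{off}$, measurable by FRAP — and that the *net* unbinding flux predicts
the macroscopic disassembly. Writing

$$K_{dis} = k_{off} - k_{on},$$

treating disassembly as a mono-exponential process gives the prediction
$y(t) = e^{-K_{dis} t}$, to be compared with decay curves measured directly
from time-lapse movies. The 1/e point of that curve, at $t = 1/K_{dis}$, is
the natural time scale of the relaxation.

## The FRAP model

### Forward model

`simulate_recovery()` solves a radially symmetric two-species
reaction–diffusion system on $0 \le r \le R_{dom}$:

* a free species $f(r,t)$ diffusing with the cytoplasmic coefficient $D_C$
  everywhere;
* a bound species $b(r,t)$ confined to the adhesion disc $r \le r_{FA}$,
  with $\partial b/\partial t = k_{on} f - k_{off} b + D_M \nabla^2 b$ and
  the matching sink/source in $f$.

$k_{on}$ is *apparent* (pseudo-first-order): it absorbs the density of
available binding sites, so both rates share units of 1/s and the
equilibrium bound fraction is $k_{on}/(k_{on}+k_{off})$. The instantaneous
bleach at $t=0$ multiplies both species by
$\exp(-K_{bleach} e^{-2r^2/w^2})$ — the Gaussian-beam profile with $e^{-2}$
radius $w$ — and the readout is the Gaussian-weighted total
$F(t) = \int (f+b)\, e^{-2r^2/w^2}\, dA$, normalized so the pre-bleach level
is 1. The printed spot size of the instrument being emulated, 0.77 µm, is
read as the $e^{-2}$ *diameter* (so $w = 0.385$ µm), consistent with a
diffraction-limited 63×/1.4 NA spot.

Two analytic limits anchor the solver:

* with no binding, $F(t)$ must equal the classical Gaussian-spot
  pure-diffusion series
  $F(t) = \sum_n \frac{(-K)^n}{n!}\frac{1}{1+n(1+2t/\tau_D)}$,
  $\tau_D = w^2/4D$ (`pure_diffusion_recovery()`); the solver agrees to
  better than 1% in sup-norm;
* with fast diffusion and a dominant bound pool, recovery approaches
  $1 - C e^{-k_{off}t}$; the fitted rate agrees with $k_{off}$ to within
  10%.

### The role of the measured pools

The fitting procedure fixes $D_C$ (from a separate short-timescale,
diffusion-only FRAP fit, `fit_diffusion()`) and the molecule pools $N_{FA}$
(in the adhesion) and $N_C$ (in an adjacent region of equal footprint,
`estimate_pools()`). At the pre-bleach steady state the model itself fixes
the bound:free ratio at $k_{on}/k_{off}$, so a consistent measurement has
$N_{FA}/N_C = k_{on}/k_{off}$: the pools are a redundant, independently
measured estimate of the equilibrium constant. `fadyn` therefore uses the
rates for both the dynamics and the pre-bleach amplitudes (anything else
would put the initial condition off steady state), and uses the supplied
$N_{FA}/N_C$ ratio to place multi-start initial values in `fit_exchange()` —
the stabilizing role the fixed pools play in the published procedure. The
synthetic generators always emit pools consistent with their rates. This was
a genuinely open design point: the alternative reading (pools as free
amplitude weights, decoupled from the rates) makes $k_{on}$ nearly
unidentifiable at $D_C \sim 1\text{–}1.5\ \mu m^2/s$, because the
reaction–diffusion coupling it would then enter through is of order
$k_{on} r_{FA}^2 / D_C \sim 10^{-3}$.

With amplitudes tied to the rates, both parameters are well identified: the
amplitude split between the fast (diffusive) and slow (exchange) recovery
phases determines $k_{on}/k_{off}$, and the slow-phase rate determines
$k_{off}$.

### Numerics

Conservative finite volumes on a uniform radial grid (spacing $w/20$ by
default; an error is raised beyond $w/10$), reflecting outer boundary at
$R_{dom} = 10$ µm, Crank–Nicolson ($\theta = 1/2$) stepping implemented in
compiled code with the bound species eliminated algebraically per step. A
fixed step bounded by an explicit-scheme CFL criterion would waste the
unconditional stability of the implicit scheme, so the solver instead starts
at $dt_0 = \tau_D/200$ (resolving the fast diffusive phase) and grows the
step geometrically (factor 1.08) up to a cap set by the exchange rates. With
$K_{bleach}=0$ the scheme conserves $\int (f+b)\,dA$ to rounding error;
post-bleach mass is conserved to $<0.1\%$.

`fit_exchange()` minimizes the SSR over $(k_{on}, k_{off}, K_{bleach})$ in
log space with Nelder–Mead, multi-started from a $4\times4$ logarithmic grid
over $[10^{-4}, 10^{-1}]\ s^{-1}$ plus pool-ratio-informed starts; the
16 + 4 starts are screened by SSR and the best three polished. Ties are
broken toward smaller $k_{off}$; estimates at the grid boundary set a
warning flag.

## The imaging chain

* **Background**: white top-hat with a 2 µm disc
  (`subtract_local_background()`). The cell boundary is an intensity step
  and a top-hat across it leaves a bright rim, so frames are first flattened
  by filling the outside of the cell mask with the in-cell median.
* **Segmentation** (`segment_frame()`): Gaussian smoothing (σ = 1 px),
  robust threshold median + 6·MAD (Otsu assumes a bimodal histogram that
  FA-sparse frames do not have), seeds at local maxima separated by
  ≥ 0.5 µm, marker-controlled watershed on the inverted smoothed intensity,
  minimum region area 0.2 µm². Each region gets ~32 geometric and intensity
  features (the published pipeline reports "~30"; the exact list is not
  public, so this set is a superset sufficient for tracking and decay
  analysis).
* **Tracking** (`link_tracks()`): greedy nearest-neighbour linking gated at
  1 µm with ≤ 1-frame gaps. At 3-min sampling FAs are essentially
  stationary, so global assignment would buy nothing and greedy linking is
  deterministic (ties by distance, then label). A track missing more frames
  than the gap allowance is dead at `last_seen + 1` (half-open intervals);
  "complete disassembly" is operationalized as disappearance from
  segmentation, so the segmentation threshold defines death consistently
  for synthetic and real data.
* **Peripheral vs central** (`classify_location()`): normalized distance
  from the cell boundary (EDT / in-mask maximum); peripheral iff
  $d \le 0.25$. The source imagery draws this distinction visually without
  a numeric threshold; 0.25 is exposed in the configuration.
* **Photobleaching** (`estimate_bleach_correction()`): reference = mean
  cytoplasmic intensity over the cell mask excluding dilated FA pixels (so
  genuine FA disassembly is not corrected away), dark level subtracted,
  optionally smoothed by a mono-exponential fit.
* **Decay measurement** (`intensity_decay_curve()`): by default each
  cohort track is measured on its *fixed* footprint taken at the drug frame
  (dilated 2 px), as raw sum minus a ring-median local background. Summing
  only above-threshold pixels per frame would make a decaying Gaussian blob
  appear to decay much faster than its amplitude (the thresholded area
  shrinks as the peak falls); the fixed footprint of a shape-invariant blob
  decays exactly as its amplitude. The per-frame-segmentation variant is
  retained (dead tracks then contribute 0 rather than being dropped, which
  would bias the decay shallow).
* **Time constants** (`fit_single_exponential()`): least squares of
  $e^{-t/\tau}$ with amplitude fixed to 1 (curves are normalized at drug
  time); a free-amplitude variant exists. Comparison window 0–60 min,
  > 2 time constants of the slowest group.

## The synthetic world

`generate_movie()` renders 2-h movies at 3-min intervals: anisotropic 2-D
Gaussian blobs (σ = axis length / 2.355, i.e. axes are FWHMs — a hard
ellipse would not resemble diffraction-blurred TIRF data and would not give
watershed-separable touching pairs) on an elliptical cell, peak amplitudes
500–800 photons over a 100-photon cytoplasmic background, Poisson shot noise
plus 3-photon read noise, global photobleaching with τ = 300 min (mild: the
correction is exercised, not dominant). After the drug frame each adhesion's
amplitude decays with its group τ (defaults 7.5 / 16 / 26.5 min — the
midpoints of the published 7–8 / ~16 / 25–28 min ranges), central adhesions
1.5× faster by default (the reported regime is 1.3–2×). An adhesion is dead
in the ground truth when its decay factor falls below 5% of the pre-drug
peak — an exponential never reaches zero, so a finite ground-truth lifespan
needs a threshold; 5% is configurable. Births of new, drug-insensitive
adhesions are a Poisson process with default rate 0, so recovery tests are
clean. Spatial density and blob sizes are chosen for testability; the source
reports no size distribution.

`generate_frap_dataset()` adds i.i.d. Gaussian relative noise to the exact
forward solution; 20–30 curves at ~2% noise, normalized to a pre-bleach mean
of 1 and averaged aligned at the bleach point (`normalize_and_average()`),
is the emulated operating point.

What a green test establishes is therefore internal consistency: the
analysis recovers what the generator put in, under realistic noise,
blur, bleaching, and segmentation effects. It does not establish that real
FAs decay mono-exponentially, that blob shapes are Gaussian, or that the
5% death threshold matches any biological endpoint.

## End-to-end closure

`run_pipeline()` ties both branches to one ground truth per protein: a group
τ fixes $K_{dis} = 1/\tau$ (in 1/min), the post-drug FRAP rates are chosen
as $k_{on} = \kappa\, k_{off}$ with $k_{off}(1-\kappa) = K_{dis}/60$
(default $\kappa = 0.5$, a disassembly state, as observed for every protein
after the drug), and the movie decays with the same τ. The pipeline then
predicts the disassembly curve from the *fitted* FRAP rates and measures it
from the *segmented* movie; agreement (RMS ≤ 0.05, implied-rate ratio in
[0.8, 1.25], rank concordance 1 across the three groups) closes the loop.
The peripheral curve is the comparison target, since the headline group τ
values refer to peripheral FAs; central curves are reported alongside.

Degenerate inputs are handled without crashing: flat curves flag
non-convergence, empty frames segment to zero records, an empty cohort is an
error naming the stage, and non-physical parameters are rejected naming the
offending field.

## Known limitations

* The exchange model has a single binding class; proteins with two
  exchange timescales would need a triple-state model (out of scope).
* The apparent $k_{on}$ is treated as constant during disassembly, although
  the mechanism it summarizes (progressive loss of binding sites) makes it
  time-dependent; the prediction is therefore expected to run slightly
  *fast* relative to measurement on real data. No correction factor is
  applied.
* Whether measured disassembly curves should be survival or intensity
  curves is ambiguous in the source; both are produced, and the comparison
  accepts either.
* No FA splitting/merging, no sliding, no flat-field or registration
  corrections; the TIFF layer covers only the uncompressed 16-bit baseline
  subset.
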