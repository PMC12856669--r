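---
title: "Quantifying light-switchable protein-protein interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying light-switchable protein-protein interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoppi)
```

## The system and the model

`photoppi` analyzes interactions in which a small photoreceptor — the
motivating case is a cyanobacteriochrome (CBCR) GAF domain carrying a bilin
chromophore — binds a partner protein with different affinities in its dark
(red-absorbing, Pr) and light (green-absorbing, Pg) states. Four species
matter: the free and partner-bound forms of each photostate. The package
parameterizes this cycle with

* $k_u$ — thermal reversion rate of the *unbound* light state (1/s),
* $k_b$ — thermal reversion rate of the *bound* light state (1/s),
* $K_{d,D}$, $K_{d,L}$ — partner dissociation constants of the dark and
  light states (M).

Under the coupling assumption used throughout (a switching quantum-yield
factor of 1, which `four_state_model()` hard-fixes), detailed balance around
the cycle forces

$$\frac{k_b}{k_u} = \frac{K_{d,L}}{K_{d,D}},$$

so the ratio of reversion rates *is* the photoswitch selectivity. The model
object carries a `consistent` flag that verifies this identity to $10^{-9}$
relative; `k_b` may also be set freely to represent hypothetical
non-conforming pairs.

### From reversion kinetics to the dark-state affinity

When light-state binding equilibrates fast relative to reversion
(rapid-equilibrium assumption), the observed reversion rate at free binder
concentration $B$ is the population-weighted average implemented by
`effective_rate()`:

$$k_{\mathrm{eff}}(B) =
  \frac{k_u + k_b\, B/K_{d,L}}{1 + B/K_{d,L}}.$$

For $B \ll K_{d,L}$ and a conforming pair this reduces to the working linear
law fitted in practice,

$$k_{obs} = k_u\!\left(1 + \frac{B_{tot}}{K_{d,D}}\right),$$

so a straight-line fit of $k_{obs}$ versus total binder ($B_{tot}$, free
binder approximated by total in the excess-binder regime) yields $k_u$ as
the intercept and $K_{d,D}$ as intercept/slope (`fit_reversion_series()`,
weighted by $1/\mathrm{SE}^2$ when per-trace rate errors are available,
unweighted otherwise — the weighting convention is a package choice; delta-
method standard errors from the regression covariance). Within the validity
region $B_{tot} \le 0.05\,K_{d,L}$ the linearization deviates from the exact
rate by at most 5% (`selfcheck()` verifies this over a random sweep), and a
warning is emitted when $\max(B_{tot})/K_{d,L} > 0.1$. Individual traces are
fitted as single exponentials $A e^{-kt} + c$ with `fit_exponential()`
(Levenberg–Marquardt; rate initialized from a log-linear regression of the
baseline-subtracted signal, the baseline from the final 5% of points; flat
or non-convergent traces return a flagged failure, never a silent number).

Because the linear law is itself an approximation, a noiseless
generate-then-fit cycle is an exact identity only when the generator uses
the same law: `gen_reversion_traces(rate_law = "linearized")` exists for
that purpose, while the default `"rapid-equilibrium"` generation carries
the (bounded) linearization bias — about 1.4% in $K_{d,D}$ at the default
conditions below. A further validation route, `reversion_ode_trace()`,
integrates explicit association/dissociation kinetics (default association
rate $10^6\ \mathrm{M^{-1}s^{-1}}$) and converges to the rapid-equilibrium
prediction; it is a numerical cross-check, not an exposed inference path.

### Equilibrium titrations and thermodynamics

Fluorescence titrations are fitted to a 1:1 isotherm
$F(B) = F_0 + \Delta F \cdot f_b(B)$ where `fraction_bound_exact()` solves
the mass-balance quadratic with the cancellation-free root, accounting for
receptor depletion. Depletion is the default because measured affinities in
this regime (0.6–7 µM) are close to practical receptor concentrations; the
hyperbolic form is selectable and agrees within 1% whenever
$R_{tot} \le 0.01\,K_d$. Free energies use
$\Delta G = RT \ln K_d$ with $R = 1.987204\times10^{-3}$ kcal/(mol K) and a
1 M standard state, default $T = 298.15$ K. Unmeasurably weak binding is
carried as an explicit lower bound (`fold_selectivity()` propagates an
`is_lower_bound` flag) rather than a sentinel number.

## Chemical-shift-perturbation calling

`cspmap` implements a deliberately formulaic classifier over paired
\(^1\mathrm{H}\)–\(^{15}\mathrm{N}\) HSQC peak lists:

1. **Assignment transfer** (`match_peaks()`): each reference peak takes the
   nearest perturbed peak inside a tolerance box (defaults
   $\pm 0.05$ ppm \(^1\)H, $\pm 0.5$ ppm \(^{15}\)N — typical amide
   reproducibility; the tolerances are configurable). An empty box with
   exactly one peak in the 3× box is still transferred (a strongly shifted
   peak); an empty 3× box means the peak *vanished* (exchange broadening);
   any multiplicity — two candidates for one reference, or one perturbed
   peak claimed by two references — marks every residue involved
   *ambiguous* and excludes it from all further analysis. Perturbed peaks
   weaker than 5% of the median reference intensity (the `intensity_floor`)
   do not count as present, formalizing "visible at a low contour level".
2. **Metrics**: per matched residue, the intensity ratio
   (perturbed/reference) and the composite shift metric
   $S = 5\,|\Delta\delta_H| + |\Delta\delta_N|$.
3. **Calls** (`call_affected()`): vanished ⇒ affected, always. Over
   matched, non-ambiguous residues compute the mean ratio $m_I$ and mean
   metric $m_S$; a residue is affected when ratio $< m_I/2$ **or**
   $S > 2\,m_S$, with strict inequalities so a residue exactly on a
   threshold is deterministically unaffected. Vanished and ambiguous
   residues are excluded from both means — including vanished peaks at
   ratio 0 would drag $m_I$ down and inflate the affected set.

Because both thresholds are intensity *ratios* and shift differences, calls
are invariant to uniform rescaling of either spectrum's intensities, but
adding or removing residues moves the means and can, legitimately, flip
borderline calls; a test documents this sensitivity. The affected set is
exported one residue per line (`export_active_residues()`) in the form
docking programs take as "active residue" ambiguous interaction restraints,
and `set_overlap()` gives intersection/Jaccard statistics for comparing,
e.g., binder-affected versus photoswitching-affected sets under identical
thresholds.

## Trajectory post-processing

Frames are 1-based (R convention; PDB `MODEL` numbers map directly),
coordinates in Å.

* **Superposition**: `superpose()` computes the Kabsch least-squares rigid
  fit via SVD, guaranteeing a proper rotation (det $= +1$) and rejecting
  collinear selections. Tests cross-check against `bio3d` and a direct
  numerical minimization.
* **Stability window**: `detect_stable_window()` replaces by-inspection
  selection with a definition: the longest contiguous window covering at
  least 20% of frames whose Cα-RMSD spread stays within 1 Å (both
  configurable), ties resolved toward the latest window since equilibrated
  segments come late. An exhaustive window search serves as the test
  oracle.
* **Medoid frame**: after superposing every frame onto a common reference
  over an alignment selection (receptor Cα of nonterminal residues —
  default trims 5 residues per terminus, configurable since terminal fraying
  is not part of the binding mode), `medoid_frame()` scores each window
  frame $i$ by $\sum_n \sum_j d^n_{ij}$, the displacement of scored atom
  $n$ between frames $i$ and $j$ summed over scored atoms and window
  frames, returning the minimizer (ties → lowest index). The single-
  reference alignment is equivalent to all-versus-all alignment up to fit
  noise because the metric is computed in the common frame; the brute-force
  oracle in the tests quantifies exactly this. Whether $j$ ranges over the
  window only (default, "similarity within the stable region") or all
  frames is a flag.
* **H-bond occupancy**: a frame satisfies the bond when donor–acceptor
  distance $\le 3.0$ Å and donor–hydrogen–acceptor angle $\ge 135^\circ$
  (a common trajectory-analysis convention; both cutoffs are parameters of
  `hbond_criterion()` and recorded in reports — note the choice of
  donor–acceptor rather than hydrogen–acceptor distance is itself a
  convention). `hbond_occupancy()` reports per-replicate percentages and
  their mean ± sample SD across replicates.

## What the synthetic data does and does not emulate

The `gen_*` generators produce every input type with recorded ground truth
(`ground_truth()`, serialized as JSON) and byte-identical output under a
repeated seed. Noise is additive i.i.d. Gaussian everywhere — magnitudes
are user parameters — because nothing finer (photon statistics, NMR
lineshapes, force-field physics) is in scope.

Defaults mirror the study conditions the package targets: $k_u = 0.0116$
s⁻¹ (≈1 min half-life), $K_{d,D} = 3$ µM, $K_{d,L} = 1$ mM, binder grid
0–8 µM with a binder-free point, 200 points over 300 s, 1%-of-amplitude
noise (a realistic plate-reader scale); titrations at $K_d = 7$ µM,
0.5 µM receptor (the instrument-level receptor concentration is not a
published number, so the default is a plausible fluorescence working
concentration and is configurable), a 12-point grid to 100 µM, 1% noise;
peak lists of 120 residues with 15 affected at (0.05, 0.4) ppm and shift
noise (0.002, 0.02) ppm; toy trajectories of 100 frames with a 30-frame
drift phase and 0.3 Å jitter, in three replicates.

Two constructions are deliberately idealized:

* Synthetic amide peaks are placed on a seeded, jittered grid whose cells
  are wider than the matching tolerance plus the effect size, so
  ground-truth recovery is well-posed. Real HSQC spectra contain genuine
  overlap; passing recall tests therefore demonstrate the classifier's
  correctness, not its robustness to crowding (the ambiguity machinery is
  what handles crowding, and it is tested separately on constructed
  collisions).
* Toy trajectories drift by 4 Å/frame before the stable phase — far
  steeper than a relaxing MD trajectory — so the stable window is
  unambiguous by construction, and the scheduled H-bond triple is placed
  analytically (collinear D–H···A at 2.8 Å when on, 4.5 Å when off) and
  excluded from jitter so occupancy equals the schedule exactly. Chains are
  helical poly-alanine-like traces with explicit amide protons; nothing
  about force-field realism is claimed.

Problem sizes in the tests and the acceptance script (50 kinetic seeds,
20 peak-list seeds, 50 twenty-frame medoid toys, 1000-frame occupancy
schedules) were chosen as the smallest sizes at which the Monte-Carlo
summaries are stable.

## End-to-end runs

`run_pipeline()` executes simulate → fit-kinetics → fit-titration → csp →
trajectory stages from a single seed, writing per-stage TSV/CSV outputs, a
plain-text report and `metrics.json`; every report embeds the seed and an
MD5 hash of the resolved configuration, and a stage failure leaves a
`FAILED` marker naming the stage. Configuration files are flat
`key = value` text with `[section]` scoping (`parse_run_config()`), with
concentrations in µM at the surface and molar internally. `selfcheck()`
re-runs the built-in brute-force oracles (medoid double loop,
quadratic-versus-hyperbolic dilute limit, linearization bound) and prints a
flat pass/fail summary.

```{r, eval = FALSE}
cfg <- default_run_config(seed = 11, out_dir = "demo_run")
metrics <- run_pipeline(cfg)
selfcheck()
```

## Known limitations

* The kinetic route infers $K_{d,L}$ only as a bound through the validity
  check; photostationary-state modeling under continuous illumination is
  out of scope.
* The CSP classifier is threshold-based by design; it does not model
  exchange regimes or fit titration-course CSPs.
* Trajectory input is multi-model PDB only; binary trajectory formats are
  intentionally unsupported to keep I/O dependencies light.
* Cooperative or non-1:1 binding models are not provided; the titration
  machinery assumes the stoichiometry has been established independently.
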