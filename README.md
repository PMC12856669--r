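# photoppi

Quantitative analysis of **light-switchable protein–protein interactions**:
the kind of system in which a small photoreceptor (e.g. a cyanobacteriochrome
GAF domain) binds a partner tightly in one photostate and weakly in the
other, so that red light drives dissociation and thermal reversion restores
the complex. The package is aimed at biophysicists characterizing such
switch/binder pairs from standard bench data — UV–vis kinetic traces,
fluorescence titrations, HSQC peak lists, and MD trajectories of the
modeled complex.

## What it computes

**Kinetics → affinity.** For a conforming pair the bound/unbound thermal
reversion rates satisfy `k_b/k_u = K_d,L/K_d,D`, and for total binder far
below `K_d,L` the observed reversion rate follows

    k_obs = k_u (1 + B_tot / K_d,D)

so a (weighted) line through `k_obs` versus `B_tot` yields the unbound rate
`k_u` (intercept) and the dark-state dissociation constant `K_d,D`
(intercept/slope), with delta-method standard errors. Individual traces are
fitted as `A·exp(−k t) + c`; the exact rapid-equilibrium rate law, its
linearization bound, and an explicit-association ODE cross-check are all
implemented.

**Equilibrium titrations.** 1:1 isotherm fits with receptor depletion
(exact mass-balance quadratic, stable root), plus thermodynamic conversions
`ΔG = RT ln K_d` and fold-selectivity with explicit lower-bound propagation
for unmeasurably weak states.

**NMR chemical-shift-perturbation mapping.** Sparky-style peak-list I/O,
assignment transfer with ambiguity exclusion, the composite shift metric
`S = 5|ΔδH| + |ΔδN|`, intensity ratios, and the threshold rule *affected ⇔
ratio < mean/2 or S > 2·mean* (vanished peaks affected by definition). The
affected set exports directly as docking "active residue" restraints.

**Trajectory post-processing.** Kabsch superposition, Cα-RMSD stability
windows (formalized longest-window definition), the representative-frame
(medoid) selection minimizing `Σ_n Σ_j d_ij^n` over scored atoms, and
hydrogen-bond occupancy (donor–acceptor ≤ 3.0 Å, D–H···A ≥ 135°) with
mean ± sd across replicates. Multi-model PDB in and out.

**Synthetic data.** `gen_*` generators emulate all four input types with
recorded ground truth and seed-exact determinism, so the entire pipeline
runs and validates itself with no external data.

## Worked example

```r
library(photoppi)
metrics <- run_pipeline(default_run_config(seed = 11, out_dir = "demo_run"))
```

```
[fit-kinetics] K_d,D = 3.05 uM (k_u = 0.01164 /s)
[fit-titration] K_d = 6.94 uM; fold selectivity >= 328
[csp] 15 affected residues (Jaccard vs truth 1.000)
[traj] stable window 31..100; medoid frame 78; H-bond 96.2 +/- 0.82 %
```

`demo_run/report.txt` then reads:

```
photoswitchable-interaction pipeline report
seed: 11    config md5: 365ce53ce55b87e4e3b8e67cce9ba21e

[kinetics]  K_d,D = 3.05 +/- 0.016 uM; k_u = 0.01164 /s (t1/2 = 59.6 s)
[titration] K_d = 6.94 +/- 0.28 uM; dG = -7.04 kcal/mol; selectivity >= 328-fold
[csp]       15 affected residues -> active_residues.txt
[traj]      stable window 31..100 (frames); medoid frame 78; H-bond occupancy 96.2 +/- 0.82 % (n = 3 replicates)
```

Reading the numbers: the kinetic route recovers the dark-state affinity
(generated at 3 µM) as 3.05 ± 0.02 µM with an unbound-state half-life of
about one minute; the independent titration route gives 6.94 µM against its
own 7 µM ground truth; the perturbation caller recovers exactly the 15
seeded residues and writes them as docking restraints; and the trajectory
stage finds the stable window after the scheduled 30-frame drift, picks a
representative frame from it, and reports the scheduled hydrogen-bond
occupancy across three replicates. `run_pipeline` is deterministic: the
same seed reproduces `metrics.json` byte for byte.

Individual steps are plain functions, e.g.:

```r
deltaG_from_Kd(2.6e-6)                       # -7.619 kcal/mol at 25 C
fold_selectivity(200e-6, 7e-6, TRUE)$value   # >= 28.6-fold
selfcheck()                                  # built-in brute-force oracles
```

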