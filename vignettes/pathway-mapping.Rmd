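---
title: "Mapping the free-energy pathway of Rad4-DNA lesion recognition"
author: "lesionPMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the free-energy pathway of Rad4-DNA lesion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionPMF)
```

## The problem

Rad4 (the yeast orthologue of human XPC) is the damage sensor of nucleotide
excision repair. It recognizes UV-induced cyclobutane pyrimidine dimers
(CPDs) through a sequence of slow conformational events: association of its
BHD2/BHD3 domains with the DNA, flipping of the two adenines opposite the
lesion (the partner bases 5'-dA and 3'-dA) out of the duplex, and insertion
of the BHD3 beta-hairpin into the vacated lesion site. Each event can be
assigned a scalar collective variable (CV) -- a distance between the
mass-weighted centers of mass (COMs) of two atom groups:

* `eta` -- COM of the BHD3 beta-hairpin backbone to the COM of the sugar
  rings of the lesion-flanking bases (hairpin insertion);
* `gamma`, `gamma_prime` -- COM of 5'-dA to the COM of the binding-pocket
  residues TYR375/MET376/ASN377 (5'-dA flipping, in two model contexts);
* `delta` -- COM of 3'-dA to the COM of PHE434 (3'-dA flipping);
* `xi` -- COM of the flanking-nucleotide sugar rings to the COM of the
  BHD2/BHD3 pocket backbone (Rad4-DNA association).

The free energy along each CV, the potential of mean force (PMF)
$F(x) = -k_\mathrm{B}T \ln \rho(x)$, is estimated by umbrella sampling:
a series of biased simulations, each restrained by a harmonic potential
$w_i(x) = \tfrac{k_i}{2}(x - c_i)^2$ at a different center $c_i$, combined
by the weighted histogram analysis method (WHAM). Comparing the PMFs of
rival model states then orders the events into a recognition pathway.

This package implements that entire analysis chain as reusable, testable
components. The one deliberate substitution is the sampler: instead of
all-atom biased MD (out of scope here), biased CV samples come from an
overdamped Langevin engine on analytic toy landscapes with known features.
Because WHAM and the downstream feature extraction only see per-window CV
samples, every stage runs identically on real biased-MD output read with
`readUmbrellaRun()`.

## Collective variables on structures

`parseStructure()` reads fixed-column PDB (via bio3d), keeping only blank
or `'A'` alternate locations and assigning masses from the element column
(falling back to the first alphabetic character of the atom name). COMs
are mass-weighted by default; a geometric-center option exists but is off
because the construction is explicitly a center of *mass*. Atom-name
conventions are the standard ones: protein backbone N/CA/C/O; DNA backbone
P/OP1/OP2/O5'/C5'/C4'/C3'/O3'; sugar ring C1'-C4'/O4'; "heavy" excludes H
and D. Residue numbering follows the source file verbatim -- published
residue labels are mapped through the user's chain/residue selections, so a
deposition whose numbering differs from the literature labels is handled by
the caller's mapping, not by guesswork in the parser.

Two open conventions were settled as follows: the binding-pocket COM uses
*all* heavy atoms of TYR375/MET376/ASN377 (not side chains only), matching
the wording "heavy atoms of the binding pocket residues"; and
`gamma_prime` uses the same geometric construction as `gamma`, since the
published description of the fourth flipping study is internally
inconsistent about which base it tracks.

## The umbrella protocol

`buildSchedule()` places windows inclusively from `xMin` to `xMax`; the
four canonical schedules are 1-22.5 Å for `eta` (44 windows, k 75/5),
4-19.5 Å for `gamma` (32, k 100/10), 2-16.5 Å for `delta` (30, k 100/10)
and 10-30 Å for `xi` (41, k 100/10), all spaced 0.5 Å
(`canonicalSchedules()`). Each window runs two stages: a strong-constant
(k_eq) equilibration that drags the system to the window center and is
discarded, then a weak-constant (k_prod) production stage that *resumes
from the equilibration endpoint* and supplies the WHAM samples. The
default 1:30 ratio of equilibration to production samples mirrors the
200 ps : 6 ns protocol of the source study; the absolute desk-scale
defaults (2 000 / 60 000 samples) were chosen so a full schedule runs in
seconds while leaving per-bin statistical noise well below the features
being read (tenths of kcal/mol).

The two DNA base-pair restraints that keep the lesion-flanking pairs
crystalline (targets 6.06 Å and 5.85 Å, k = 25 kcal mol^-1 Å^-2) cannot be
realized by a 1-D engine; they are carried as metadata and emitted by
`exportBiasConfig()` in PLUMED-style text (COM/DISTANCE/RESTRAINT lines
plus one umbrella line per window) for use with a real MD engine.

## The Langevin engine

`simulateBiased()` propagates overdamped (Brownian) dynamics,

$$x \leftarrow x - \frac{D}{k_\mathrm{B}T}\bigl(F'(x) + w'(x)\bigr)\,
\mathrm{d}t + \sqrt{2D\,\mathrm{d}t}\;\mathcal{N}(0,1),$$

because only the stationary Boltzmann distribution matters for WHAM;
inertial dynamics would add parameters without adding information.
Defaults: D = 1 Å²/ps, T = 300 K, kB = 0.0019872041 kcal/mol/K (so
kT = 0.59616 kcal/mol). Numerical points worth knowing:

* **Stability.** The Euler-Maruyama step is stable only if
  $\theta = D k\,\mathrm{d}t/k_\mathrm{B}T < 0.2$ for the stiffest
  harmonic term; this is validated at run time. The default dt = 0.01 ps
  suits biases up to ~11 kcal/mol/Å²; protocols carrying the canonical
  equilibration constants (75-100) use dt = 0.001 ps.
* **Discretization bias.** For a harmonic term the sampled variance is
  inflated by $1/(1 - \theta/2)$. At dt = 0.01 with k = 10 that is ~9%;
  at dt = 0.002 it is under 2%. Analyses that check the Boltzmann variance
  therefore run at dt ≤ 0.002 ps.
* **Force evaluation.** The landscape force is tabulated once on a 0.002 Å
  grid and interpolated linearly inside a compiled kernel; the
  interpolation error is negligible against the statistical noise.
* **Determinism.** All noise comes from R's RNG; per-window seeds derive
  deterministically from the master seed and window index, so runs are
  reproducible file-for-file.
* **Divergence guard.** A trajectory leaving the landscape domain by more
  than 5 Å aborts with a divergence error -- the signature of an unstable
  time step. Confinement is the landscape's job (quartic walls), not the
  integrator's.

## Toy landscapes and what they do (not) emulate

`makeDoubleWell()` builds two negative Gaussians plus quartic confining
walls, with depths solved so the planted well positions, barrier height
(measured from the first well) and well asymmetry are met exactly; the
registry of features stored with every landscape is re-derived by a dense
numerical scan, so tests always compare against scan-verified ground
truth. `makeWellPlusPlateau()` emulates the 3'-dA profile shape (steep
steric wall, stacking well, intrahelical plateau); `makePiecewiseLandscape()`
interpolates arbitrary published profile shapes through knots.

`makeToyComplex()` plants exact COM-COM distances by building symmetric
atom groups (their COM is exact by symmetry) in disjoint chains, plus
inert decoration atoms; `makePlantedEnsemble()` adds iid Gaussian
coordinate noise with per-component sd jitter/sqrt(3), so the expected
RMSD of a copy to its center equals the requested jitter.

These generators emulate the *statistics* the pipeline consumes --
Boltzmann-distributed CV samples under harmonic biases, and ensembles with
planted conformational clusters. They do not emulate molecular geometry,
chemistry, multi-dimensional CV coupling, or the slow orthogonal degrees
of freedom that make real umbrella windows hysteretic. Passing tests
therefore certify the estimators and decision logic, not the convergence
of any particular MD campaign.

## WHAM

`wham()` iterates the standard self-consistent equations

$$\rho(x_b) = \frac{\sum_i n_i(x_b)}{\sum_i N_i
\exp[(f_i - w_i(x_b))/k_\mathrm{B}T]},\qquad
f_i = -k_\mathrm{B}T \ln \sum_b \rho(x_b) e^{-w_i(x_b)/k_\mathrm{B}T},$$

to convergence (max |Δf_i| < 1e-7 kcal/mol by default, 0.1 Å bins,
at most 1e5 direct iterations), then anchors F = -kT ln ρ at zero. Only
production samples enter. Bins with zero counts are masked; stray outlier
bins holding under 0.1% of the samples are trimmed from the support edges,
and a zero-count gap splitting the remaining support is an error rather
than something to silently bridge -- features must never be computed
across unsampled territory. `bootstrapUncertainty()` uses within-window
moving-block resampling with the block length set to twice the integrated
autocorrelation time, re-running WHAM per replicate.

## Reading features off a PMF

`findMinima()` smooths with a 3-bin moving average and filters by
prominence (default 0.25 kcal/mol -- the published profiles are read by
eye, so the thresholds here are the package's own, chosen to ignore noise
at the size the bootstrap reports while keeping every feature the study
names). `barrierBetween()` reports the interior argmax with heights from
both flanking minima; the single published number (3.19 kcal/mol at 12.1 Å
between the 10.4/14.2 Å wells) corresponds to the metastable-side
convention. `crossoverPoint()` fits a harmonic around a minimum
(half-width 1.5 Å, the quoted elastic-regime half-width) and reports the
first grid point deviating by more than 1 kcal/mol -- the elastic-cage
break of the inserted hairpin, read near 4.5 Å / ~13 kcal/mol.
`plateauRegions()` uses a centered finite-difference slope below
0.2 kcal/mol/Å over at least 3 Å. `deinsertionEnergy()` reproduces the
worked arithmetic |46.77 - 41.81| = 4.96 kcal/mol and has a profile
overload that reads both magnitudes off two PMFs.

## Metastable states

`clusterEnsemble()` implements GROMOS neighbour counting: repeatedly take
the structure with the most neighbours within the RMSD cutoff (default
1.5 Å) as a center, remove its cluster, repeat. Two conventions are ours:
the center is a *medoid* (an actual member), never an averaged structure,
because averaging can break chemistry; and when neighbour counts tie --
which is the norm when the cutoff comfortably exceeds the cluster radius --
the tie breaks to the member with the least summed RMSD to its neighbours,
so the reported center is the most central member rather than an arbitrary
one. Superposition uses Kabsch with the proper-rotation guard
(det R = +1 always). `selectMetastable()` restricts an ensemble to a
shoulder range of the PMF (8-13.5 Å in the deinsertion analysis), clusters
it, and returns the top cluster's center with its CV value and relative
free energy.

## Ordering the events

`compareModels()` encodes the study's decision rule: two PMFs represent
rival hypotheses about which of two events happens first; the one with the
lower free energy at a probe CV value (e.g. gamma ~ 10 Å) describes the
preferred arrangement. Margins below 0.5 kcal/mol (~kT) are declared
indeterminate -- the study treats ~3 kcal/mol as decisive and is silent
below that, so the threshold sits an order of magnitude under the decisive
scale. `inferPathway()` topologically sorts the events and *requires* the
order to be unique; contradictions and under-determination are errors, not
silently resolved.

`syntheticScenario()` packages six toy landscapes whose pairwise
energetics mirror the study's comparisons (association cheap with bases
intrahelical; 5'-dA flipping ~3 kcal/mol cheaper with 3'-dA in; insertion
downhill only with bases out). `runPathway()` drives the whole chain from
a YAML/list config -- sampling, WHAM, features, decisions, order, report.
Problem sizes in the scenario (windows of 0.5 Å, 6 000 production samples
per window, dt = 0.001 ps) were chosen so the decision margins exceed the
sampling noise by an order of magnitude while the full six-profile run
completes in seconds.

```{r scenario, eval = FALSE}
res <- runPathway(syntheticScenario(seed = 1))
res$order
#> [1] "association" "flip_5prime" "flip_3prime" "hairpin_insertion"
```

## Known limitations

* One-dimensional CVs only: no 2-D WHAM/MBAR, no replica exchange, no
  concerted (simultaneous two-base) flipping pathway.
* The engine's multi-distance restraints exist only as exported config;
  the 1-D dynamics cannot realize them.
* Published headline magnitudes from the all-atom study (e.g. the 41.81 /
  46.77 kcal/mol insertion magnitudes) are reproduced here only on
  synthetic landscapes built to those readings; nothing in this package
  re-derives them from molecular physics.
* The crystal-structure check of `eta` (≈4.95 Å on the deposited complex)
  needs the PDB deposition plus a residue mapping and is therefore an
  optional, user-supplied analysis, not a shipped test.
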