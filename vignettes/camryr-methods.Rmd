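---
title: "Models and methods behind camryr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind camryr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camryr)
```

# Scope

camryr analyses the recognition between calmodulin (CaM) — the ubiquitous
four-EF-hand Ca^2+^ sensor — and the CaMBD2 calmodulin-binding peptides of
the ryanodine receptor Ca^2+^-release channels RyR1 (skeletal muscle,
K3614–L3644) and RyR2 (cardiac muscle, R3581–L3611). The package covers the
quantitative layers such a study needs: equilibrium binding (fluorescence
titrations), binding thermodynamics (isothermal titration calorimetry,
ITC), binding kinetics (surface plasmon resonance, SPR), conformational-
ensemble analytics (RMSF, essential-dynamics PCA, RMSIP, replica
consistency), and protein structure network (PSN) topology including the
Communication Robustness (CR) index between EF-hand Ca^2+^-binding loops.
Seeded synthetic-data generators emulate every input, so the complete
pipeline runs and is tested without instrument files or molecular-dynamics
trajectories.

Residue numbering throughout refers to the mature CaM protein lacking the
initiator methionine; peptide residues carry channel numbering.

# Equilibrium binding

A fixed concentration $L$ of peptide is titrated with protein at total
concentration $x$. The observable (the emission-peak wavelength of the
peptide's single tryptophan) is rescaled to a fraction bound

$$f_b = \frac{y - y_0}{y_{max} - y_0},$$

where $y_0$ and $y_{max}$ are the free-peptide and saturated-complex
endpoints. Two isotherms are available:

* **hyperbolic** (default): $f_b = x/(K_D + x)$ on the total titrant
  concentration. This is the classical one-site saturation function.
* **quadratic_depletion**: the exact 1:1 mass-balance root
  $f_b = \big[(x + L + K_D) - \sqrt{(x + L + K_D)^2 - 4xL}\big]/(2L)$.

Both are exposed and reported side by side because the typical working
condition ($L = 1\ \mu M$ peptide with $K_D \sim 10{-}300$ nM) makes ligand
depletion material: the hyperbolic form then returns an *apparent* $K_D$
inflated by roughly $L/2$. Endpoints are free fit parameters by default —
pinning them to the first/last observed points (available via
`endpoints = "pinned"`) is exactly the $f_b$ formula but biases $K_D$
whenever the final titration point has not truly saturated the peptide.
Per-replica fits are never pooled; replicate $K_D$ values are aggregated
as mean ± s.d. with Welch t-tests for pairwise comparison
(`aggregate_kd()`).

Free energies use $\Delta G = RT\ln K_D$ with $R = 1.9872 \times 10^{-3}$
kcal mol^-1^ K^-1^, $T = 298.15$ K for 25 °C, and a 1 M standard state;
`make_thermo_record()` closes the cycle with $-T\Delta S = \Delta G -
\Delta H$, and `ddg()` forms $\Delta\Delta G = \Delta G_{mut} -
\Delta G_{WT}$ only for records sharing peptide and temperature.

# Isothermal titration calorimetry

`itc_forward()` implements the one-set-of-sites model for a perfusion
cell. Each injection of volume $v$ into the cell of volume $V_0$
instantaneously displaces a fraction $v/V_0$ of the well-mixed content, so
cell-species and titrant concentrations follow the recursions
$M_i = M_{i-1}(1 - v_i/V_0)$ and
$X_i = X_{i-1}(1 - v_i/V_0) + X_{syr}\, v_i/V_0$. The complex
concentration after injection $i$ is the quadratic mass-balance root with
binding-site concentration $N M_i$, and the measured heat is

$$q_i = V_0\, \Delta H\, \big( [MX]_i - [MX]_{i-1}(1 - v_i/V_0) \big),$$

i.e. the change in complex net of the complex carried out with the
displaced volume. This is the standard displacement model used by open
ITC fitters; the forward model is verified in the test suite against an
independent per-injection root-finding oracle. Heats are normalised to
kcal per mole of injectant before fitting. The fitter estimates $N$,
$K_D$ and $\Delta H$ by Levenberg–Marquardt least squares with $K_D$
parameterised as $\log_{10} K_D$ (the likelihood is extremely flat in
linear $K_D$ at high Wiseman $c = M_{cell}/K_D$) and a small multistart
over $\log_{10} K_D$. A $c$ outside 1–1000 triggers a reliability
warning. First-injection discard is available but off by default. Blank
(heat-of-dilution) subtraction is element-wise (`subtract_dilution()`).

The default protocol — 200 µL cell with 10 µM protein, thirty 1 µL
injections of 125 µM peptide at 298.15 K — reflects common practice for
CaM–peptide titrations and puts nanomolar $K_D$s at $c \approx 10^3$,
which is why the recovery study asserts a 20% tolerance on $K_D$ but 5%
on $\Delta H$: near the upper end of the reliable $c$ window the isotherm
shape constrains the enthalpy much more tightly than the affinity.

# SPR kinetics

Sensorgrams follow a 1:1 Langmuir scheme with pseudo-first-order
association and single-exponential dissociation, under the two-stage
procedure: the **dissociation phase is fitted first**,
$R(t) = R_0 e^{-k_{off} t}$, and the association phase is then fitted
with $k_{off}$ fixed, $R(t) = R_{eq}(1 - e^{-k_{obs} t})$ with
$k_{obs} = k_{on} C + k_{off}$, so $k_{on} = (k_{obs} - k_{off})/C$.
A fitted $k_{obs} \le k_{off}$ is reported as an explicit error (it
signals a mislabelled analyte concentration or an unusable $k_{off}$).
Per-curve rate constants across a concentration series are aggregated as
mean ± s.e.m. and the kinetic dissociation constant is
$K_D^{kin} = k_{off}/k_{on}$, exactly, by construction. `koff_mode`
chooses between per-curve dissociation fits (default) and a single global
$k_{off}$ fixed for every association fit; both modes are provided
because the staging of the published two-step procedures varies between
instruments. Phase windows default to 60 s association and 300 s
dissociation. Injection-artifact masking and bulk refractive-index
offsets are not modelled beyond an optional drift term in the
dissociation fit.

`kinetic_fold_change()` reports variant-over-reference rate ratios with
first-order error propagation and Welch t-tests on per-curve constants —
the quantity of interest when asking whether a disease variant associates
or dissociates faster than wild type (kinetic discrimination).

# Ensemble analytics

An `ensemble` is an $F \times P \times 3$ coordinate array. `superpose()`
performs a least-squares rigid-body fit (Kabsch, proper rotations only)
of every frame onto the iteratively refined mean structure (two
refinement rounds by default); the fit selection defaults to all
particles, and typical use fits on Cα while ions ride along and are
assessed by `rmsf()` separately. RMSF is
$\sqrt{\langle |r_f - \bar r|^2 \rangle_f}$ per particle.

Note that superposition estimates 6 rigid degrees of freedom per frame
from $3P$ coordinates, so for pure isotropic jitter of width $\sigma$ the
post-fit RMSF converges to $\sigma\sqrt{3}$ only up to a factor
$\sqrt{1 - 6/3P}$; the property tests therefore use $P = 50$ particles,
where the deficit is about 2%.

`pca_ensemble()` diagonalises the $3P \times 3P$ coordinate covariance
(no mass weighting, matching Cα-only essential dynamics); eigenvalues are
clipped at zero against round-off. `project_frames()` gives per-frame
scores whose variances equal the eigenvalues. Subspace similarity uses

$$\mathrm{RMSIP} = \sqrt{\frac{1}{S}\sum_{n=1}^{S}\sum_{m=1}^{S}
(v_n^i \cdot v_m^j)^2},$$

with $S = 20$ by default; RMSIP is 1 for identical essential subspaces
and has expectation $\sqrt{S/3P}$ for random subspaces, which the tests
verify by Monte-Carlo draws (and against the bio3d implementation).

`replica_consistency()` classifies projection scores by replica label
with linear discriminant analysis: consistent replicas leave the
classifier at chance accuracy. Because a density plot is not a
comparable scalar, the pairwise overlap is summarised by the
Bhattacharyya coefficient of per-replica Gaussian fits in the first two
score dimensions — 1 for identical sampling, 0 for disjoint clouds. When
two replicas are numerically identical LDA has nothing to separate; this
is reported as chance accuracy rather than an error.

# Protein structure networks

Frame-wise non-bonded interaction records (hydrogen-bond, electrostatic,
hydrophobic) are condensed into per-pair **persistence** — the fraction
of frames in which the contact is present, duplicates within a frame
counted once (`persistence_from_records()`). The persistence threshold
$p_T$ is chosen from the size of the largest hydrophobic cluster:
`select_pt()` scans a grid, builds the hydrophobic-only graph at each
candidate, and returns the last grid point before the steepest drop of
the largest-connected-component curve — the most inclusive network
consistent with the dissolution transition, with ties resolved to the
smaller threshold and a fallback of 0.2 (with a warning) for flat or
degenerate curves. `build_psn()` then keeps pairs with persistence
$\ge p_T$, merging interaction classes by maximum persistence by default
(sum is available; the merge rule is configurable because published
pipelines differ on it).

Topology: `hubs()` reports degree centrality, the hub set (degree > 4,
i.e. more than four persistent interactions) and a comparative reporting
set of nodes reaching degree ≥ 6 in at least one of the compared
networks; `delta_degree()` gives per-node and total degree differences
between a variant and a reference network, treating nodes missing from
one graph as degree 0.

Communication between EF-hands — represented by their bidentate
Ca^2+^-coordinating glutamates E31 (EF1), E67 (EF2), E104 (EF3), E140
(EF4) — is scored by the Communication Robustness index from the number
$n_{XY}$ of distinct shortest paths of length $l$:

* default form: $CR_{XY} = n_{XY}\, p_T / l$;
* alternative form: $CR_{XY} = n_{XY}\, p_T^{\,l}$.

The compact published rendering of the index is typographically ambiguous
between these two readings. The first is the default here because it
yields values in the 0–0.5 range at plausible $p_T$, consistent with the
working robustness cutoff $CR \ge 0.1$, whereas the exponential form
collapses below 0.01 for any $l \ge 2$ at $p_T \approx 0.2$, leaving the
cutoff unusable; both forms are exposed and the choice is a configuration
flag, not an assertion about the original authors' intent. Shortest-path
counting enumerates distinct node sequences (verified against an
exhaustive DFS oracle); a disconnected pair has $CR = 0$.

# Synthetic data

Each generator is a pure function of its seed (bit-identical output,
caller's RNG stream untouched) and returns its generating truth next to
the data:

* `gen_titration()`: 0–4 µM titrant grid against 1 µM peptide,
  depletion-exact signal plus Gaussian noise, default σ = 2% of span —
  typical of emission-peak readouts.
* `gen_itc()`: forward-model heats plus Gaussian noise (default 2% of the
  largest heat) and an optional constant dilution offset with its blank.
* `gen_sensorgrams()`: 60 s / 300 s phases at 0.5 s sampling, Langmuir
  steady-state amplitudes, 1 RU Gaussian noise.
* `gen_ensemble()`: helix-like base geometry, Gaussian amplitudes along
  planted orthonormal 3P-modes, isotropic jitter (default 0.3 Å), and
  optional rigid-body nuisance motion that superposition must remove.
* `gen_interaction_records()`: independent Bernoulli frame occupancy per
  planted pair; `ef_route_template()` plants a hydrophobic clique whose
  persistence (0.45) sets the threshold knee, two node-disjoint two-step
  communication routes per EF-hand pair of interest, and transient
  distractors, with the EF1–EF3 route removed in the "mutant" condition.

What the generators deliberately do **not** emulate: instrument drift
and baseline artifacts, mass-transport limitation in SPR, conformational-
change enthalpy contributions in ITC, force-field physics, correlated
contact dynamics, or anharmonic ensemble motions. Passing recovery tests
therefore demonstrate that the estimators are correct and well-
conditioned under their own statistical assumptions at realistic noise,
not that real instrument data will fit this cleanly.

# Problem sizes and numerical choices

The test-suite and acceptance studies use: 100 seeded fluorescence
replicates (10-point titrations), 50 seeded thermograms (30 injections),
12 sensorgram curves per condition (four concentrations in triplicate),
5000-frame ensembles of 50 particles for RMSF convergence, 200
random-subspace draws in 300 dimensions for the RMSIP null, 50 random
graphs of ≤ 12 nodes for exhaustive path enumeration, and 100 seeded
network instances per condition for the discrimination rate. These sizes
keep every stochastic check's sampling error well inside its asserted
tolerance.

Other numerical choices: nonlinear fits use Levenberg–Marquardt
(minpack.lm) with data-driven starting values (half-transition point for
$K_D$, log-linear regression for exponential rates, plateau heat for
$\Delta H$); eigen-decompositions use the symmetric path and clip
negative round-off eigenvalues; rotations force det = +1; degenerate
inputs (constant titration signal, all-zero heats, non-decaying
dissociation, single replica, two-node hydrophobic networks, pairs with
no path) are explicit errors or flagged fallbacks rather than silent
results.

# Known limitations

* The published MD-scale quantities (replica RMSIP above 0.782,
  Ca^2+^-RMSF shifts of ~0.2 Å, hub ΔDegree totals, per-complex CR
  values) require microsecond trajectory ensembles and are **not**
  reproduced at desk scale; the package verifies the machinery by its
  analytic and planted-truth properties instead.
* ITC fitting assumes integrated heats; raw power traces and baseline
  integration are out of scope, as are multi-site and sequential models.
* SPR fitting does not model surface heterogeneity, mass transport, or
  regeneration effects.
* Interaction detection from raw coordinates is intentionally decoupled:
  the PSN layer ingests pre-computed interaction records, keeping it
  agnostic to trajectory formats and detection geometry.
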