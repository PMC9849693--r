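# camryr

Binding thermodynamics, kinetics and structure-network analysis of
calmodulin–RyR peptide recognition.

## What this is for

Calmodulin (CaM), the four-EF-hand Ca²⁺ sensor, regulates the ryanodine
receptor Ca²⁺-release channels of skeletal (RyR1) and cardiac (RyR2)
muscle through a highly conserved CaM-binding region (CaMBD2). Point
mutations in CaM cause life-threatening arrhythmias (long QT syndrome,
CPVT), and a central question is how such mutations perturb CaM's
ability to discriminate between two nearly identical targets. Answering
it takes several quantitative layers at once, and `camryr` implements
all of them as one tested R pipeline for biophysicists working on
EF-hand sensor/target recognition:

- **Equilibrium binding** — fraction-bound transform
  `fb = (y − y0)/(ymax − y0)`, one-site isotherms (hyperbolic
  `x/(K_D + x)` and the exact ligand-depletion quadratic), per-replicate
  nonlinear fits, ΔG = RT ln K_D conversion, ΔΔG versus wild type.
- **Calorimetry** — one-set-of-sites ITC forward model with perfusion-
  cell displacement correction, dilution-blank subtraction, and
  least-squares estimation of N, K_D, ΔH (then ΔG and −TΔS).
- **Kinetics** — two-stage 1:1 Langmuir SPR analysis: single-exponential
  dissociation first (`k_off`), then pseudo-first-order association with
  `k_obs = k_on·C + k_off`; per-curve aggregation as mean ± s.e.m.,
  kinetic K_D = k_off/k_on, and variant/WT fold-changes with
  significance tests.
- **Ensembles** — Kabsch superposition onto the refined average
  structure, Cα/ion RMSF, essential-dynamics PCA, RMSIP subspace
  overlap, and LDA-based replica-consistency reports.
- **Structure networks** — interaction persistence from frame-wise
  contact records, persistence-threshold selection from the largest
  hydrophobic cluster, hub/ΔDegree topology, shortest-path enumeration,
  and the Communication Robustness index
  `CR_XY = n_XY · pT / l` between EF-hand representative glutamates
  (E31, E67, E104, E140), with a CR ≥ 0.1 robustness rule.
- **Synthetic data** — seeded generators emulating each input (titration
  tables, thermograms, sensorgrams, coordinate ensembles with planted
  modes, interaction records with planted communication routes), so the
  whole pipeline runs with no instrument or trajectory data.

See `vignettes/camryr-methods.Rmd` for the models, assumptions, defaults
and limitations.

## Worked example

Free-energy decomposition of measured CaM–RyR affinities, and a kinetic
fit of simulated sensorgrams:

```r
library(camryr)

## published ITC measurements (K_D in nM, ΔH in kcal/mol) -> ΔG, −TΔS, ΔΔG
thermo_table()
#>   variant peptide kd_nM     dh      dg minus_tds    ddg
#> 1      WT    RyR1 12.31  -9.94 -10.791   -0.8508     NA
#> 2    N97I    RyR1 19.93  -9.58 -10.505   -0.9254 0.2855
#> 3   Q135P    RyR1 62.03 -19.97  -9.833   10.1373 0.9582
#> 4      WT    RyR2  8.62 -11.28 -11.002    0.2781     NA
#> 5    N97I    RyR2 12.32 -10.02 -10.790   -0.7703 0.2116
#> 6   Q135P    RyR2 83.45 -16.20  -9.657    6.5431 1.3450
```

Reading the table: binding is enthalpy-driven throughout (ΔH < 0); the
Q135P variant pays a large entropic penalty (−TΔS = +10.1 and +6.5
kcal/mol) and loses the most binding free energy relative to wild type
(ΔΔG up to +1.35 kcal/mol against RyR2).

```r
## 12 simulated sensorgrams (4 concentrations x 3 replicates), two-stage fit
sim <- gen_sensorgrams(kon = 1e5, koff = 0.004,
                       concentrations = rep(c(0.25, 0.5, 1, 2) * 1e-6, 3),
                       seed = 11)
fit_langmuir_series(sim$curves)
#> <kinetic_fit> n = 12 curves
#>   kon  = 9.97e+04 +/- 4.7e+02 1/(M s)
#>   koff = 0.004 +/- 2.5e-06 1/s
#>   kinetic KD = 4.01e-08 M
```

The planted rate constants (1e5 M⁻¹s⁻¹, 0.004 s⁻¹) are recovered within
their standard errors, and the kinetic K_D (40 nM) equals k_off/k_on
exactly.

```r
## end-to-end structure-network pipeline on synthetic interaction records
run_ef_discrimination("wt", seed = 1)
#> <cr_matrix> pT = 0.5, robustness threshold 0.1
#>     EF1 EF2 EF3 EF4
#> EF1 0.0   0 0.5 0.5
#> EF2 0.0   0 0.0 0.0
#> EF3 0.5   0 0.0 0.5
#> EF4 0.5   0 0.5 0.0
```

The planted EF1–EF3 and EF3–EF4 communication routes are detected as
robust (CR ≥ 0.1) at the automatically selected persistence threshold;
in the `"mutant"` condition the EF1–EF3 entry drops to 0.

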