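# dimerhinge

Structural-ensemble analysis of hinge motion in homodimeric enzymes, driven
by small-angle X-ray scattering (SAXS).

Loss-of-function variants of homodimeric enzymes such as aromatic amino acid
decarboxylase (AADC) often leave the crystal structure almost unchanged while
altering the *solution* behaviour of the dimer: the two chains open about a
hinge axis, flexible loops lose or gain mobility, and catalytic residues are
mispositioned. `dimerhinge` implements the analysis chain used to detect and
quantify this situation:

1. **Ensemble screening against SAXS data.** For every frame of a conformer
   ensemble (e.g. from molecular dynamics) a theoretical profile is computed
   with the Debye formula,

   I(q) = Σᵢ Σⱼ fᵢ fⱼ sin(q·rᵢⱼ)/(q·rᵢⱼ),

   scaled onto the experimental curve by weighted least squares, and scored
   by χ² = (1/(n−p)) Σₖ [(I_exp(qₖ) − c·I_calc(qₖ) − b)/σₖ]². The frame with
   minimal χ² is the model in best agreement with the data. Guinier analysis
   (ln I ≈ ln I₀ − q²Rg²/3) supplies the primary SAXS parameters.

2. **A fixed 13-variable hinge descriptor panel** for a two-chain dimer:
   distances from the dimer center C to each chain center (C–C_A, C–C_B) and
   to two marker residues per chain (defaults 173 and 470, the helix-6 probe
   and hinge-axis residues of AADC numbering); the inter-chain marker
   distances 173A–173B and 470A–470B; the angles C_A–C–C_B and 173A–C–173B;
   the signed hinge dihedral 173A–470A–470B–173B; and the chain A/B
   asymmetry pair: normalized spatial discrepancy (NSD_AB) and alignment
   quality Q = N²_align / ((1+(RMSD/r₀)²)·n_a·n_b).

3. **Cross-species comparison by PCA** of labeled descriptor tables
   (correlation-matrix PCA with a deterministic sign convention), which
   separates open-hinge from closed-hinge species and shows *which*
   geometric variables carry the separation.

4. **Ensemble flexibility and correlated motion**: per-residue RMSF with the
   harmonic B-factor conversion B = (8π²/3)·RMSF², RMSD/Rg series, gromos
   neighbour-count clustering on the pairwise superposed-RMSD matrix, the
   dynamics cross-correlation matrix (DCCM) and region-block summaries (e.g.
   a mobile loop against the helix it is coupled to).

5. **Structure I/O and bookkeeping**: PDB reading/writing (single- and
   multi-model), SAXS `.dat` curves, detection of unmodeled
   (missing-electron-density) residue stretches, Kabsch superposition.

A first-class synthetic-data module generates C2-symmetric bead dimers with
a controllable hinge dihedral, thermal noise, inflated-mobility loops, noisy
SAXS experiments and crystal mimics with missing loops, so the entire
pipeline can be exercised and validated without any external data.

## Worked example

Build a 20-frame hinge-opening ensemble (dihedral 0–38° in 2° steps, 0.5 Å
thermal noise), simulate a noisy SAXS experiment from frame 8 (θ = 14°), and
recover it:

```r
library(dimerhinge)

spec <- hinge_ensemble_spec(n_res = 120, marker1 = 40, marker2 = 110,
                            theta_list = seq(0, 38, by = 2),
                            sigma_thermal = 0.5, seed = 42)
ens  <- generate_hinge_ensemble(spec)
expc <- synth_saxs_experiment(ensemble_frame(ens, 8), noise_frac = 0.02,
                              seed = 43)

scr <- screen_ensemble(ens, expc)
scr$best_frame
#> [1] 8
round(scr$chi2_per_frame[scr$best_frame], 3)
#> [1] 0.781

pan <- descriptor_panel(ensemble_frame(ens, scr$best_frame),
                        marker1 = 40, marker2 = 110)
round(pan[, c("d_173A_173B", "d_470A_470B", "ang_173A_C_173B",
              "dih_173A_470A_470B_173B", "NSD_AB", "Q_AB")], 3)
#>   d_173A_173B d_470A_470B ang_173A_C_173B dih_173A_470A_470B_173B NSD_AB Q_AB
#> 1      22.989      78.728          70.723                  14.061  0.555 0.62
```

The χ² of the selected frame is ≈ 0.8 (consistent with the 2% error model),
and the measured hinge dihedral of the selected frame is 14.06° — the value
the generator imposed before thermal noise. The probe distance 173A–173B
responds to the hinge, while the axis distance 470A–470B does not: that pair
is the hinge signature the descriptor panel is designed to expose. The
chain-asymmetry scores (NSD_AB > 0, Q_AB < 1) quantify how far thermal noise
has taken the dimer from exact C2 symmetry.

Guinier analysis of the same frame's computed profile agrees with the
coordinate radius of gyration to ~2%:

```r
g <- guinier_fit(debye_profile(coords(ensemble_frame(ens, 8)),
                               q_grid = seq(0.001, 0.3, length.out = 200)))
round(c(guinier = g$rg, coordinate = radius_of_gyration(coords(ensemble_frame(ens, 8)))), 2)
#> guinier coordinate
#>   28.48      29.05
```

For multi-species comparisons, `run_saxs_pipeline()` orchestrates
screening → descriptors → PCA per species from one configuration and writes
deterministic TSV/JSON outputs; `run_dynamics_pipeline()` does the same for
RMSF/DCCM/clustering. A command-line front end is installed at
`inst/cli/dimerhinge` (subcommands `simulate`, `profile`, `fit`, `screen`,
`descriptors`, `pca`, `rmsf`, `dccm`, `cluster`, `compare`, `asymmetry`,
`gaps`, `run-saxs`, `run-dynamics`).

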