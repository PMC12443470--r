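---
title: "Quantifying hinge motion in homodimers from SAXS-screened ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hinge motion in homodimers from SAXS-screened ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerhinge)
```

## The problem

A homodimeric enzyme can lose function without any large change in its
crystal structure. One recurring mechanism is a *hinge motion*: the two
chains rotate about an axis through a pair of equivalent residues (one per
chain), separating distal structural elements — in AADC-like numbering, a
rotation about the axis through the two residues 470 that increases the
separation of the two residues 173 on the apical helices. Crystal packing
suppresses the motion, so it must be read out of *solution* data: an
ensemble of conformers (typically from molecular dynamics) is screened
against an experimental SAXS curve, the best-fitting conformer per species
is selected, and the geometry of the selected models is compared across
wild type and variants.

`dimerhinge` implements that analysis chain: profile calculation and
chi-square screening, a fixed geometric descriptor panel, PCA comparison,
and ensemble statistics (RMSF/B-factor, clustering, correlated motion). It
also ships a synthetic-data generator so every stage can be validated
end-to-end with known ground truth.

## Models and procedures

### Scattering and screening

Theoretical profiles use the Debye formula over a weighted point set,
$I(q) = \sum_{ij} f_i f_j \,\mathrm{sinc}(q r_{ij})$, with the
$\mathrm{sinc}$ limit at $q = 0$ giving $I(0) = (\sum_i f_i)^2$ exactly.
The default form-factor model is one unit-weight bead per C-alpha. No
hydration shell or excluded-volume corrections are applied: absolute
intensities therefore differ from atomistic predictors such as crysol, but
per-frame *ranking* — which is what model selection needs — depends only on
relative profile shape. Absolute chi-square values from atomistic fitting
programs are consequently not comparable and are not reproduced.

Fitting minimizes $\sum_k [(I_{exp,k} - c I_{calc,k} - b)/\sigma_k]^2$ in
closed form (weighted least squares), with the background term $b$ off by
default. The chi-square denominator is configurable ($n$, $n-1$, $n-p$;
default $n-p$) because conventions differ across fitting programs. Curves
without uncertainties get a uniform substitute $\sigma = 0.01 \max I_{exp}$
and the result is flagged. Screening computes profiles directly on the
experimental q-grid, so an exact self-match yields chi-square ~ 0 with no
interpolation bias; interpolation (linear in q, never extrapolating) is
still available when fitting externally computed curves on a foreign grid.
Ties in the per-frame chi-square ranking resolve to the lowest frame index.

Guinier analysis fits $\ln I$ against $q^2$ by weighted regression inside
the window $q R_g \le 1.3$ (configurable), iterated to self-consistency on
$R_g$ starting from the smallest-q points; at least three points must
remain or the fit is refused.

### The descriptor panel

Thirteen variables, in a fixed declared order so loadings stay comparable
across runs: C–C_A, C–C_B, C–173A, C–173B, C–470A, C–470B, d(173A,173B),
d(470A,470B), angle C_A–C–C_B, angle 173A–C–173B, dihedral
173A–470A–470B–173B, NSD_AB, Q_AB. Centers are geometric (unit-weight)
centers over all atoms — a mass model would add a parameter without
changing the hinge signal on C-alpha models — and marker positions are
C-alpha atoms. The dihedral is reported signed, in (−180°, 180°], with the
right-hand convention about the 470A→470B axis. Note that swapping the
chain labels reverses the four dihedral points *in order*, which leaves a
signed dihedral unchanged; the A/B-indexed distances swap, and NSD/Q are
symmetric by construction.

NSD (normalized spatial discrepancy) is the superposition-minimized,
nearest-neighbour-normalized discrepancy of two bead sets. Its published
uses do not document the minimization, so the package fixes one: centroid
alignment, principal-axis initialization over the four proper axis-sign
combinations (both mapping directions), then Nelder-Mead refinement of the
six rigid parameters from the two best starts. The procedure is
deterministic and matches a 10-degree rotation-grid brute force on test
shapes; because it is a numerical minimization, NSD values are reproducible
to optimizer precision (~1e-4), not machine precision. Q uses the SSM
convention $Q = N_{align}^2 / ((1+(\mathrm{RMSD}/r_0)^2) n_a n_b)$ with
$r_0 = 3$ Å.

### Ensemble statistics

RMSF and DCCM superpose every frame onto the ensemble mean in two passes
(fit to the initial mean, recompute, refit), which removes the reference
bias of fitting to an arbitrary frame at negligible cost. RMSF is the root
*mean* square deviation (population convention; cross-checks against tools
using the $n-1$ sample convention must rescale by $\sqrt{(M-1)/M}$).
B-factors follow $B = (8\pi^2/3)\,\mathrm{RMSF}^2$ exactly. Zero-variance
atoms in the DCCM produce a warning and a zeroed row/column with unit
diagonal rather than an error, so crystal-frozen regions do not abort a
pipeline.

Gromos clustering takes the pairwise superposed-RMSD matrix and repeatedly
extracts the frame with the most neighbours within a cutoff. The cutoff has
*no default*: trajectory-analysis suites conventionally state it in nm, and
a value copied from a methods section without unit conversion changes the
result by 10x (0.30 nm = 3 Å; a literal "30 Å" would merge almost any
protein ensemble into one cluster). Requiring the caller to state the value
in Angstrom makes that decision explicit.

Region-block DCCM summaries default to nothing; for AADC-like analyses the
natural blocks are the flexible loop (residues 324–357, catalytic loop
327–341) against the apical helix around residue 173 (the 170–180 stretch
is the documented interpretation of "helix 6", whose bounds are not stated
numerically in the source literature).

### PCA comparison

Descriptor tables mix Angstrom, degrees and unitless scores, so the default
is correlation-matrix PCA (z-scored columns); covariance mode is a flag.
Constant columns are dropped with a warning rather than producing NaN
z-scores. Signs are fixed by making the largest-magnitude entry of each
loading column positive. Species separation is read from the scores;
*which* variables separate is read from the loadings — in a hinge-opening
scenario the dihedral and the probe distance d(173A,173B) dominate while
the axis distance d(470A,470B) and the asymmetry scores stay near the
origin.

## What the generator emulates — and what it does not

`make_dimer_template()` builds chain A as a single toroidal coil sampled at
an exact 3.8 Å consecutive C-alpha spacing (the virtual-bond length), with
coil pitch above 4 Å so the curve does not self-intersect, and dimensions
comparable to a compact 480-residue chain. Chain B is the exact C2 image,
then rotated about the marker-2 axis so the template's hinge dihedral is
exactly zero: the template *is* the closed reference state. Frames of
`generate_hinge_ensemble()` rotate chain B rigidly about the axis through
the two marker-2 beads to impose a prescribed dihedral exactly (the probe
distance then grows monotonically with the angle while the axis distance is
invariant — the defining hinge signature), and add i.i.d. Gaussian
displacements (default SD 0.5 Å per axis, a typical thermal C-alpha
amplitude), multiplied by 3 inside the flexible-loop interval (default
324–357 where the chain is long enough — the AADC loop3 numbering — else
the central fifth of the chain).

`synth_saxs_experiment()` perturbs the true Debye curve multiplicatively,
$I_{exp} = I_{true}(1+\epsilon)$, $\epsilon \sim N(0, 0.02)$ by default,
and reports $\sigma_q = 0.02\,I_{true}(q) + 10^{-5} \max I_{true}$. The
multiplicative term mimics synchrotron batch error bars; the small additive
floor stands for detector background. The floor must stay far below the
intensity maximum: a dimer's forward scattering exceeds its wide-angle
intensity by about four orders of magnitude, so a floor at even 0.1% of
$\max I$ would dominate every informative error bar and flatten the
chi-square landscape.

What the generator deliberately does **not** model: side chains, cofactors
and sequence (beads are identical); realistic force-field sampling
(frames are prescribed rigid states plus isotropic noise, not Boltzmann
samples); counting statistics and inter-point noise correlation in SAXS;
hydration-shell contrast. Passing tests therefore demonstrate that the
*analysis* is correct and well-calibrated under its stated error model —
they do not certify performance on real detector data, where systematic
errors (buffer mismatch, aggregation) dominate long before the 2% regime.

## Problem sizes and numerical choices

Validation studies run on a desk-scale dimer of 120 residues per chain with
markers at residues 40 (probe) and 110 (axis), which preserves the geometry
of the full-size construction while keeping each descriptor panel around a
second; the full 480-residue template is used where the AADC residue
numbering itself matters (missing-stretch mimics of 323–341, 19 residues,
and 323–354, 32 residues). Monte Carlo checks use 100 seeds for frame
recovery at 2% noise (20 frames, 2-degree hinge steps, recovery within one
step), M = 10000 frames for the isotropic-jitter RMSF limit
($\mathrm{RMSF} \to \sigma\sqrt{3}$), and M = 2000 for the DCCM null bound
$|C| < 3/\sqrt{M}$. Cross-species PCA uses three synthetic species (hinge
means 5°, 20°, 25° — a closed-like reference against two open variants)
with eight frames each.

Numerical edge cases are pinned down as follows: the Debye sum handles
$q = 0$ through the sinc limit, not exclusion; superposition refuses fewer
than three or collinear correspondence points and never returns a
reflection; degenerate dihedrals (flank on the central axis) and
zero-length angle arms are errors; PCA refuses fewer than three rows or
two non-constant variables; all generators require an explicit seed
whenever they draw random numbers.

## Known limitations

Chi-square values are comparable only within one form-factor model and one
sigma convention; the package never mixes conventions silently but cannot
prevent the caller from comparing its values with atomistic-fitting
outputs. NSD minimization is local after a deterministic multi-start; for
pathological shapes (near-symmetric decoys) the reported value can be a
local minimum, which the rotation-grid oracle in the test suite bounds for
the shapes exercised. Gap detection works on author residue numbering and
rejects insertion codes. The PDB writer emits coordinates at the format's
fixed 3-decimal precision, so round-trips are exact only to 1e-3 Å.
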