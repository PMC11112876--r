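---
title: "Methods: hemichannel trajectory metrics and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemichannel trajectory metrics and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexchannel)
```

## The problem

Connexin hemichannels are hexamers of four-transmembrane-helix (TM1–TM4)
protomers. Each protomer of several connexins carries an *intracellular
pocket*: a cytoplasm-facing cavity lined by residues from all four TM
helices and stabilised by intra-protomer salt bridges (in connexin50,
prominently R33–E162, with K158–E223 nearby). Molecular-dynamics studies
characterise this pocket through a small set of trajectory metrics:

* **Salt-bridge occupancy** — the fraction of frames in which the
  centers of mass of two residues' terminal moieties (guanidinium of
  Arg, carboxylate of Glu/Asp, amide of Gln, terminal amine of Lys) are
  at interacting distance, ≤ 4 Å.
* **TM–TM distances** — the Cα–Cα distance between the residues closest
  to the centers of mass of two helices (25/159 for TM1–TM3, 85/220 for
  TM2–TM4).
* **TM inclinations** — the angle between the best-fit straight line
  through the Cα atoms of TM1 and that of each other helix.
* **Pocket hydration** — the number of water molecules within 6.0 Å of
  the center of mass of the Cα atoms of the 30 pocket-lining residues, a
  proxy for pocket volume.
* **RMSD / RMSF** — global stability and per-residue flexibility after
  Kabsch superposition.
* **Per-protomer statistics** — box-plot summaries over all frames of
  all replicas, and Kruskal–Wallis tests of each protomer's metric
  distribution against a reference condition at p < 0.05.

`hexchannel` implements this analysis layer as reusable, tested code
over multi-model PDB input, and ships a synthetic hexamer generator that
plants every quantity the metrics estimate, so the whole pipeline can be
validated against known ground truth without any external data.

## Metric definitions and numerical choices

**Moiety centers of mass.** Distances between charged residues use the
mass-weighted center of the terminal-moiety atom set, not single atoms.
The guanidinium set is {CZ, NH1, NH2, NE}; carboxylates include the
carbon center ({CD, OE1, OE2} for Glu, {CG, OD1, OD2} for Asp); the Gln
amide is {CD, OE1, NE2}; Lys uses NZ. Arg/Glu/Gln are the classic
definitions for this analysis; Lys and Asp are included because K158
bridges are part of the pocket's interaction network. The map is a
plain configurable list (`default_moiety_map()`).

**Bridge classification.** Published analyses call a protomer
"bridge-forming" without stating an occupancy rule; we classify a pair
as bridged when occupancy ≥ 0.5 of the analysed frames, and expose the
threshold. Occupancy itself uses the ≤ 4 Å criterion frame by frame.

**Axis fitting.** "Best straight line through the Cα atoms" is
implemented as total least squares: the first principal direction of the
centered coordinates. It is rotation-equivariant and unique up to sign;
the sign is fixed by residue order (N→C), so a topologically
antiparallel helix reads ≈ 180°, preserving orientation information
rather than folding angles to [0°, 90°]. Note that the TLS axis of a
*finite* ideal helix deviates slightly (≈ 1.4° at 22 residues,
100°/residue) from the geometric axis because the sampled phases do not
balance; this is a property of the estimator, not an error, and the
synthetic generator compensates for it (below).

**RMSD/RMSF.** RMSD superposes each frame's Cα selection onto a
reference frame with the Kabsch algorithm (SVD with determinant
correction, so reflections are never returned) under uniform weights —
the convention for per-residue profiles. RMSF uses a two-pass
alignment: align to frame 1, form the mean structure, re-align to the
mean, and report the root mean square distance of each Cα from its mean
position. For isotropic per-coordinate jitter of s.d. σ the expected
RMSF is σ√3, shrunk by the ≈ 6/(3M) share of variance the rigid-body
alignment absorbs for M atoms; the validation suite checks exactly this
closed form.

**Pocket hydration.** The pocket centroid is recomputed every frame
(the Cα set it is bound to moves); a fixed-centroid mode exists for
comparison. Distances are measured to the water oxygen only — one
oxygen per molecule is what the count means — and the 6.0 Å boundary is
inclusive. Waters are recognised by residue name (HOH/TIP3/SOL/WAT).
Pocket residues missing from a model (e.g. unmodelled termini) are
dropped with a warning; only a protomer with *no* pocket residues is an
error, whereas the representative-residue metrics fail hard, because
those name exact residues.

**Statistics.** Quartiles use linear interpolation between order
statistics (quantile type 7) with Tukey 1.5·IQR whiskers and outliers;
the convention is recorded in the run metadata because box-plot numbers
depend on it. The Kruskal–Wallis H is tie-corrected with a chi-square
approximation (df = k − 1); the per-protomer sample sizes here (frames
× replicas) make the approximation comfortable, and all-identical input
degenerates to H = 0, p = 1. Mutant-vs-reference comparisons apply the
same two-group rank test per protomer, pooled over frames and replicas,
without multiple-testing correction by default (a Bonferroni option
exists). Replica aggregation uses the sample s.d. (n − 1); pooled
distributions concatenate all frames from all replicas.

**Input conventions.** Multi-model PDB (fixed-column v3.3), ATOM and
HETATM, altloc other than ' '/'A' dropped with a warning, hydrogens
optional (all metrics are heavy-atom based). Frames are assumed
whole-molecule imaged; no periodic-boundary correction is applied.
Frame spacing (`dt_ps`) is metadata supplied by the caller, never
inferred. A frame-range option windows the analysis; the default is all
frames.

## The synthetic generator

`build_hexamer()` places six protomers with 6-fold symmetry on a 25 Å
ring. Each protomer is four ideal helices (rise 1.5 Å/residue,
100°/residue, radius 2.3 Å, 22 residues) on the corners of a square
whose diagonals — TM1–TM3 and TM2–TM4 — are 11 Å; TM2/TM4 run
antiparallel to TM1/TM3. Residue numbering (TM1 15–36, TM2 75–96, TM3
144–165, TM4 210–231) places the representative residues 25/85/159/220
and 27 of the 30 pocket-lining residues inside the modelled segments
(9, 12, 13 lie N-terminal of TM1 and are not modelled; the generated
channel config lists the 27 present). Helix phases are chosen so the
representative Cα atoms sit at equal height facing the same direction,
making the planted Cα–Cα distances equal the axis separation; and each
helix is rotated so its *exact TLS axis* coincides with the intended
direction, which makes the manifest a fixed point of the analysis: at
zero jitter every planted distance and angle is recovered to floating
precision.

Only the atoms the metrics touch are emitted: Cα backbone, the moiety
atoms of residues 23/33/158/162/223 (laid out with zero-mean offsets so
the moiety COM is exactly the planted center), and single-oxygen HOH
waters. Salt-bridge plants displace the mobile residue's moiety along
the fixed→mobile direction to an exact COM distance: the bridged
distance (3.5 Å by default) on the first ⌈dwell·n⌉ frames and 6.0 Å
otherwise, so occupancy targets are met exactly; a stochastic dwell
mode exists for calibration tests. Twelve pocket waters per protomer
are sampled uniformly in a 5 Å sphere around each pocket centroid
(inside the 6 Å counting cutoff with margin) and 150 bulk waters
outside 7.5 Å of every centroid, so planted counts are exact before
jitter. Finally, seeded Gaussian jitter (default σ = 0.15 Å, a modest
thermal-fluctuation scale) is added per coordinate per frame; the seed
fixes the output bit-for-bit.

`perturb_protomer()` applies a rigid rotation of one protomer (and its
planted pocket waters, which travel with it) about a membrane-plane
axis through its centroid. Being rigid, it changes the protomer's axis
*directions* but leaves all intra-protomer metrics invariant — a
property the tests assert. Inclination changes are instead planted
through per-helix tilts (`tm_tilts`), which rotate a single helix about
its own centroid.

What the generator does *not* emulate: sterics, side-chain rotamers,
membrane atoms, correlated motions, periodic boundaries, or real
connexin coordinates. Passing tests therefore demonstrate that the
estimators recover the statistical structure they assume (planted
geometry plus isotropic noise), not that any biological conclusion
holds on real trajectories.

## Validation design

The test suite works oracle-first: pocket counts are compared with a
brute-force per-water distance scan; Kabsch RMSD for mirror-image
inputs with a rotation-grid scan plus refinement; Kruskal–Wallis H with
the direct rank-sum formula; RMSF with the σ√3 closed form;
superposition and all metrics with rigid-motion invariance under random
rotations. Estimator consistency is checked at two frame counts (20
vs 400; frame-averaged errors shrink under jitter), with the TM3
inclination planted at 12° so the angle estimator sits away from the 0°
fold point, where the folded noise distribution would otherwise put a
floor under the error. Validation problem sizes (a few frames and tens
of waters for oracle-equivalence sweeps over 20 seeds, 2,000 frames for
the RMSF closed form, 2,000 simulations for the type-I error of the
rank test at α = 0.05 against its binomial confidence band) were chosen
to give tight Monte-Carlo bounds while keeping the suite fast.

`scripts/acceptance.R` re-runs the headline computations from scratch —
generation, analysis, recovery — for a given `--seed` and writes the
resulting numbers as JSON.

## Worked example

```{r example}
b <- build_hexamer(synthesis_params(n_frames = 10, seed = 42))
tr <- b$trajectory
ch <- b$channel

# salt-bridge occupancy per protomer for the 158-223 pair
bridged_protomer_count(tr, ch, c(158, 223))

# TM geometry of protomer A
mean(tm_distance(tr, ch, "A", "TM1-TM3"))
mean(tm_inclination(tr, ch, "A", "TM3"))

# pocket hydration, pooled over protomers
s <- pocket_water_series(tr, ch, quiet = TRUE)
summary(s$pooled)
```

## Limitations

* The analysis assumes whole-molecule-imaged frames; trajectories with
  molecules wrapped across periodic boundaries must be re-imaged
  upstream.
* TM segment ranges are construct-specific and must come from
  configuration; there is no universal default.
* The chi-square approximation of the rank test is used at all sample
  sizes; for very small groups an exact permutation approach would be
  preferable.
* Binary trajectory formats (XTC/DCD/TRR) are out of scope; convert to
  multi-model PDB first.
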