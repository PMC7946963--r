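---
title: "Models and methods behind firclaw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind firclaw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firclaw)
```

This vignette records the models the package implements, the defaults
it chooses where the underlying experimental literature leaves a
choice open, and what the synthetic-data generators can and cannot
stand in for.

## The FIR/LIR core grammar

FIP200's C-terminal Claw domain recognizes short linear motifs on
autophagy receptors. The grammar implemented here is the five-residue
core `psi-Theta-x-x-Gamma`:

* `psi` ∈ {D, E, pS, pT} — the anchor. Acidic anchors define Mode I
  (phosphorylation-independent binding); phospho-S/T anchors define
  Mode II (binding created by phosphorylation). With
  `allow_conditional = TRUE`, unmodified S/T is admitted and labeled
  `conditional_II`: a latent site that a kinase could switch on.
* `Theta` ∈ {I, L, V, F, Y, W} — fills the large hydrophobic pocket
  (LHP). Restricting `Theta` to the aromatic subset {F, Y, W} gives the
  canonical LIR grammar, which is therefore a strict subset of the FIR
  grammar (`scan_lir_cores()`; the inclusion is enforced by a property
  test).
* `Gamma` ∈ {L, I, V} — docks the small hydrophobic groove (SHG).

Design choices worth recording:

* **Phospho-Tyr never satisfies `psi`.** Only Ser/Thr phosphorylation
  is implicated in anchor formation; the parser still accepts `pY`
  marks so tyrosine-phosphorylated peptides can be massed and
  fragmented.
* **The extension profile is a flag, not a filter.** Effective binding
  in either mode is supported by acidic residues and/or phospho-S/T in
  the window just N-terminal of the anchor (default `window = 4`,
  which covers the characterized E175/D176 and D102/D103/pS104
  contexts). A hit whose window contains neither is still reported,
  labeled `"core-only, low-confidence"` by `classify_mode()`. We chose
  a flag because the experimental definition gives criteria, not
  weights; no numeric composite score is invented.
* **An S/T immediately preceding the anchor is flagged as an enhancer
  site** (its phosphorylation further strengthens binding in both
  modes), again without changing the mode call.
* **All overlapping matches are reported** in ascending anchor
  position; there is no greedy suppression, since overlapping windows
  can represent genuinely alternative registers.
* Residue indexing is 1-based; protein coordinates are
  `psi_pos + offset - 1`, with offsets either supplied explicitly or
  parsed from alignment-style `>id/start-end` FASTA headers. The
  shipped example records use the characterized spans (CCPG1 FIR2 =
  99–113, Optineurin LIR peptide = 173–185), and coordinate tests pin
  the anchors to D105 and S177.

The scanner is verified against an exhaustive brute-force window check
on 1000 random phosphopeptides (lengths 5–300) in the test suite, plus
a phospho-monotonicity property: adding a phospho mark never removes a
strict hit, and can only promote `conditional_II` to `II`.

## Phosphopeptide mass arithmetic

Monoisotopic masses are used throughout (the data this supports were
acquired on a high-resolution Orbitrap); the residue table plus water
(18.010565 Da), proton (1.007276 Da) and HPO3 (79.966331 Da) are the
only constants. `[M+zH]^z+` is `(M + z·1.007276)/z`. Fragment ladders
are HCD-style b/y only — neutral-loss (−98 Da) and a/c/z series are
deliberately out of scope. Internally everything is kept at full
precision; rounding to two decimals happens only at presentation.

Peak annotation (`match_peaks()`) uses a deterministic tie-break:
smallest absolute m/z error, then higher intensity. The
`site_support` count is restricted to *site-determining* ions — those
whose residue span separates the annotated phospho position from at
least one alternative S/T/Y placement — because ions covering all or
none of the candidate sites carry no localization information.
Expected fragment masses in the tests were frozen from an independent
proteomics mass calculator rather than recomputed with the package.

## One-site FP binding model

The default model is the exact ligand-depletion quadratic

$$FB = \frac{(K_d+L_t+P_t) - \sqrt{(K_d+L_t+P_t)^2 - 4 L_t P_t}}{2 L_t}$$

with the plain hyperbola `Pt/(Pt+Kd)` selectable. At the FITC-peptide
working concentration `Lt = 0.25` µM the two agree to well under 1%
for every affinity in the preset range (9–307 µM), so the choice is
immaterial there; the depletion form remains correct when `Lt`
approaches `Kd`.

Fitting is nonlinear least squares over `{Kd, A_free, A_bound}` via
Levenberg–Marquardt, with a deterministic initializer: asymptotes from
the signals at the lowest/highest protein concentration and `Kd` from
the concentration at half-maximal signal by linear interpolation.
Non-convergence is reported honestly (`converged = FALSE` with the
optimizer's message), never silently. Standard errors come from the
Jacobian at the optimum; fold changes propagate them to first order.
Signal units are arbitrary polarization/anisotropy units; no G-factor
handling is attempted.

The titration presets encode the measured affinities as ground truth:
phospho-Optineurin LIR/Claw 12 µM, unphosphorylated 307 µM,
phospho-CCPG1 FIR2/GABARAP 9 µM, unphosphorylated 27 µM. The design —
12 two-fold protein dilutions from 0.5 µM (top 1024 µM; the weak
307 µM preset shifts to 1–2048 µM so the curve approaches
saturation), 3 replicates, homoscedastic Gaussian noise at 1% of the
signal span — mirrors a routine plate-reader titration. Note the
design ratio 307/12 ≈ 25.6; the package reports the computed ratio
and does not force it to any rounded headline value. A recovery
property test (200 simulated fits across the preset affinities) checks
that the median absolute bias stays under 5%.

What the simulator does *not* emulate: pipetting error correlated
across a dilution series, signal drift, heteroscedastic noise at high
anisotropy, or incompetent-fraction effects. Passing recovery tests
therefore shows the estimator is correct for the stated noise model,
not that every real titration is this well behaved.

## Structure interfaces

* **SASA** is Shrake–Rupley with a deterministic golden-spiral point
  set; per-element radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H
  1.20 Å and probe 1.4 Å. 960 points per atom is the working default;
  3840 is used where tight agreement with closed forms is asserted.
  Accuracy is checked three independent ways: the isolated-sphere
  closed form (exact by construction), the two-sphere spherical-cap
  formula (within 1%), and a Monte Carlo direction-set oracle on a
  multi-atom fixture (within 2%).
* **Buried surface area** is `SASA(A) + SASA(B) − SASA(AB)`. The
  literature is split between reporting this sum and its half, and
  published interface sizes rarely say which; the package computes
  both, and `calibrate_bsa_convention()` picks the convention against
  one reference interface of known published area (the apo-Claw dimer,
  ~730 Å², is the natural calibrant when deposited coordinates are at
  hand), after which the same convention should be applied uniformly.
  The per-residue decomposition sums exactly to the total.
* **Hydrogen bonds** must work without hydrogens, as deposited crystal
  structures lack them. The criterion is heavy-atom N/O donor–acceptor
  distance ≤ 3.5 Å plus an angular screen: the donor's H direction is
  estimated as opposite the centroid of its covalent bond directions,
  and the antecedent–donor–acceptor angle must be ≥ 120°. Both
  cutoffs are config-exposed (`hbond_dmax`, `hbond_angle_min`) because
  published H-bond counts depend on the program and cutoffs used; a
  count that misses by one is more often a cutoff disagreement than a
  geometry error. Backbone–backbone bonds are classed by both atoms
  being backbone N/O. The detector is validated on an idealized
  antiparallel β-strand pair with a known 2.9 Å ladder and checked
  for rigid-motion invariance.
* **Salt bridges** pair side-chain cations (Lys NZ; Arg NE/NH1/NH2;
  His ND1/NE2) with anions (Asp/Glu carboxylates and the phosphate
  oxygens of SEP/TPO/PTR, both `O1P` and `OP1` naming) within 4.0 Å —
  phosphoresidues are first-class so phospho-anchor/Arg couplings are
  detected.
* **Parsing**: altlocs resolve to highest occupancy (ties to `A`),
  waters are dropped by default, SEP/TPO/PTR are kept as polymer
  residues, model 1 of multi-model files is used, and malformed
  ATOM/HETATM records fail with their line number. Deposited residue
  numbering is taken verbatim (Claw 1490–1594; the LHP/SHG pocket
  definitions are fixed residue sets in that numbering); chain
  identifiers are discovered from the file, never hard-coded.
* **Superposition** is the Kabsch SVD solution with the reflection
  guard; degenerate (collinear/coincident) point sets are an error
  rather than an arbitrary answer. It is cross-checked against an
  independent quaternion (Horn) implementation in the tests.

The deposited complexes this grammar was derived from (PDB 7CZG, 7D0E,
7CZM, plus the earlier 6DCE and 6GMA) are not redistributed with the
package; all shipped geometry is synthetic and labeled as such. The
no-download validation surface for this module is the property suite
above — closed forms, independent oracles, and invariances — and the
toy `claw_mock` fixture that plants known LHP/SHG contacts and a
phosphate/lysine salt bridge under the real pocket numbering. Running
`run_structure_report()` on the deposited files reproduces the
published interface descriptions (a Claw/peptide interface of several
hundred Å² with a backbone H-bond ladder and phosphate salt bridges),
but that requires the user to download the coordinates.

## Numerical and reproducibility choices

* All randomness flows through explicit seeds; generators restore the
  caller's RNG state, so library code never perturbs a session's
  random stream. Re-running any pipeline with identical inputs and
  config yields byte-identical reports (stable sort orders, frozen TSV
  column order, config echoed into every summary).
* Test problem sizes: 1000-sequence scanner/oracle equivalence,
  1000-peptide fragment complementarity, 200 recovery fits, 3840-point
  SASA cross-checks. These sizes make the full suite run in well under
  a minute while keeping each property's sampling error far below its
  assertion tolerance.
* Degenerate inputs are contracts, not surprises: empty FASTA scans
  return empty reports successfully; a titration with fewer than four
  distinct concentrations refuses to fit three parameters; `d_max = 0`
  H-bond queries return empty tables; unknown elements or residues
  name themselves in the error.

## Known limitations

* The grammar is a necessary-condition screen. Many windows satisfy
  `psi-Theta-x-x-Gamma` without being functional Claw binders;
  conversely the scanner makes no attempt to score affinity. Treat
  hits as candidates for experiments, not predictions.
* Phosphosite annotations are inputs; the package deliberately does no
  phosphosite prediction.
* The FP module fits single curves; competition/displacement formats
  and global multi-curve fits are out of scope.
* Interface geometry is heavy-atom only; cation-π interactions are not
  scored, and H-bond counts inherit the cutoff sensitivity discussed
  above.
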