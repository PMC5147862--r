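---
title: "Methods: contact matrices and tight-binding affinity fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact matrices and tight-binding affinity fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raseffector)
```

# Scope

`raseffector` quantifies the interface between RAS-family GTPases and the
RAS-binding (RB) / RAS-association (RA) domains of their effectors, along two
independent lines of evidence:

* a **structural** line: residue–residue contact maps from multiple complex
  structures, aggregated on a common alignment-derived numbering into one
  interaction matrix with detected hotspot regions; and
* a **biophysical** line: equilibrium dissociation constants fitted to
  fluorescence polarization titrations with the exact tight-binding isotherm.

This vignette records the model and its assumptions, the meaning and default
of every tunable parameter, the numerical choices, and the known limitations.

# The binding model

## Assumptions

* 1:1 stoichiometry between the labeled receptor (RAS loaded with a
  fluorescent nucleotide analog) and the effector domain.
* Equilibrium is reached at every titration point.
* The polarization signal is linear in the bound fraction, between the two
  endpoints `P_free` and `P_bound`.
* Receptor depletion is **not** neglected. The receptor is held at
  `R_t = 1` µM while the tightest pairs bind with K_d near 0.05 µM, so the
  hyperbolic (Michaelis-type) approximation would be badly biased; the exact
  quadratic solution of mass action is used instead.

## Equations

With total receptor `R_t`, total ligand `E_t` and dissociation constant
`K_d`, the complex concentration `x` is the physical root of

$$x^2 - (R_t + E_t + K_d)\,x + R_t E_t = 0,$$

$$x = \frac{(R_t + E_t + K_d) - \sqrt{(R_t + E_t + K_d)^2 - 4 R_t E_t}}{2},$$

the bound fraction is `x / R_t`, and the model signal is

$$P(E_t) = P_\mathrm{free} + (P_\mathrm{bound} - P_\mathrm{free}) \cdot x / R_t.$$

`fraction_bound()` implements the root; `model_signal()` the signal;
`fit_titration()` the least-squares estimate of
`(K_d, P_free, P_bound)`.

## Numerical choices in the fitter

* **Log-scale K_d.** The optimizer works on `log K_d`, which makes the
  positivity constraint implicit and equalizes step sizes across the four
  decades spanned by the reference affinities (0.048–205 µM). The reported
  `stderr_kd` is the delta-method transform `K_d · se(log K_d)`.
* **Clamped discriminant.** Near stoichiometric binding the discriminant is
  a difference of nearly equal squares and can round below zero; it is
  clamped at zero. For `K_d = 0` exactly, the closed form
  `min(E_t, R_t)/R_t` is returned directly, because the general formula
  loses the identity `(R_t+E_t)^2 − 4 R_t E_t = (R_t−E_t)^2` in floating
  point.
* **Start values.** `P_free` and `P_bound` start at the first and last
  observed signals; `K_d` starts at the log-interpolated concentration of
  half signal (falling back to the median concentration). A deterministic
  five-entry ladder of perturbed starts is tried in order, because with
  noise-free synthetic data a machine-perfect optimum can make the post-hoc
  gradient matrix of the Levenberg–Marquardt backend singular even though
  the fit itself is exact; a slightly different approach path avoids this.
* **Backend.** `minpack.lm::nlsLM` (Levenberg–Marquardt) with
  `maxiter = 500`; convergence and the residual sum of squares are reported
  on the `binding_fit` object.

## Titration design parameters

| parameter | default | rationale |
|---|---|---|
| `receptor_total` | 1 µM | fixed labeled-receptor concentration of the assay |
| `n_points` | 24 | titration length used throughout |
| `conc_range` | 0.05–100 µM | log-spaced ligand span covering all five affinity decades |
| `p_free`, `p_bound` | 0, 1 | unit signal span for simulations; fits estimate both freely |

Units are µM end-to-end; `read_titration_tsv()` accepts an
`ligand_total_nM` column and converts.

# The structural model

## Contact definition

Two residues, one per chain, are in contact when **any** pair of their heavy
atoms lies at a Euclidean distance **≤ 4.0 Å (inclusive)**. No van-der-Waals
radius correction is applied — the criterion is a plain distance. Hydrogens,
waters and other heteroatoms are excluded before the computation; selenium
variants of standard residues (e.g. MSE) are kept and read as their standard
equivalents. Alternate locations are resolved to the highest-occupancy
conformer (ties broken by altloc identifier).

Each residue-pair record decomposes its atom pairs into four categories by
backbone membership of the two atoms — `mm`, `ms`, `sm`, `ss` — where the
backbone set is N, CA, C, O (plus OXT). A decorative `mm_hbond_like` flag
marks pairs whose backbone N···O distance is ≤ 3.5 Å, a geometry-only
hydrogen-bond proxy (no angles, no chemistry).

**Exact boundary handling.** Candidate atom pairs are found with a vectorized
squared-distance matrix using a small slack, then each candidate's distance
is recomputed with the direct `sqrt(sum(delta^2))` formula before applying
the inclusive cutoff. This makes the vectorized engine bit-identical to a
brute-force double loop, which the test suite verifies on random atom clouds.

## Alignment mapping

Rows of the interaction matrix are labeled in HRAS numbering and columns in
CRAF numbering, regardless of which homolog a structure contains. For each
chain, `map_chain()` locates the chain's sequence in its alignment row
(exact match preferred; otherwise the placement with minimum Hamming
distance at ≥ 95% identity, with a warning), then translates residue →
alignment column → reference label via `reference_numbering()`, which
numbers the reference row's non-gap columns and labels insertions with
letter suffixes ("31A").

## Matrix aggregation

`build_matrix()` has two counting modes:

* `"per-structure"` (default): a cell counts the number of structures in
  which that residue pair is in contact — at most one increment per
  structure, so cell values are bounded by the number of structures;
* `"atom-pairs"`: a cell sums contact atom pairs over all structures; the
  four category layers partition this count exactly (closure), and the total
  equals the sum of all per-record atom-pair counts (conservation).

Contacts at residues absent from the alignment maps are skipped with a
warning and itemized in a skip report; they never create new rows or
columns.

## Region detection

`detect_regions()` finds dense blocks as connected components:

| parameter | default | rationale |
|---|---|---|
| `min_count` | 2 | a cell must be supported by at least two structures (or two atom pairs) to seed a region |
| `bridge` | 1 | cells are connected within Chebyshev distance `1 + bridge`, letting one empty row/column interrupt a block without splitting it |
| `min_cells` | 3 | components smaller than three cells are noise, not regions |

Components are ranked by total count (ties: upper-left first) and labeled
R1, R2, … `hotspot_report()` then lists the top cells per region with
their dominant contact category and the fraction of structures supporting
them, plus row/column marginals. A shipped annotation
(`read_region_annotation()`) carries the canonical spans of the three
regions whose residue ranges are published (R1: RAS 37–39 × effector 66–69;
R2: RAS 21–34 × effector 83–90; R3: RAS 36/37/64 × effector 57/59/71); it is
labeling-only metadata and plays no part in detection.

# Synthetic generators and their limits

`make_toy_complex()` builds all-alanine two-chain complexes on a minimal
N/CA/C/O/CB atom template with exaggerated spacing (15 Å between atoms,
60 Å between residues, 1000 Å between chains); a planted contact relocates
one effector atom to the exact requested distance from the chosen RAS atom.
By construction every non-planted inter-chain atom pair is > 8 Å apart, so
the ground-truth contact list is exact. The price is realism: the geometry
is not stereochemically meaningful, planted distances are capped at 6 Å,
and one effector atom can serve only one planted contact.

`make_titration()` adds i.i.d. Gaussian noise to exact model signals — a
stand-in for instrument error that ignores concentration-dependent variance
and pipetting error. `make_planted_matrix()` plants rectangular constant
blocks, which are cleanly separable by design; real matrices have ragged
regions.

# Problem sizes and runtime

The package targets desk-scale problems: tens of structures with a few
hundred residues per chain, alignments with tens of rows, and 24-point
titrations. The full test suite (≈ 2 200 assertions, including 200-replicate
Monte-Carlo recovery and 50 random-cloud oracle comparisons) runs in under
a minute on one CPU; the 25-pair acceptance grid fits in seconds.

# Known limitations

* Contact detection is geometric only — no interface area, no energetics,
  no hydrogen-bond angles.
* The matrix depends on the curated alignment; mis-synchronized alignments
  silently shift rows/columns (mitigated, not removed, by the identity
  threshold and mapping warnings).
* One published fluorescence-figure legend shows a K_d inconsistent with
  the corresponding reference-table entry by a factor of ten (0.94 vs
  0.094 µM); `reference_kd_table()` follows the table, treating the legend
  value as a typographical error.
* The fitter assumes a single binding site and homoscedastic noise;
  `stderr_kd` is a local (delta-method) approximation.
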