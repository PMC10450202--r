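---
title: "Inferring domain architectures from AlphaFold2 confidence and PAE outputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring domain architectures from AlphaFold2 confidence and PAE outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdomains)
```

## The problem

AlphaFold2-class predictors emit two complementary descriptions of a
protein chain: a per-residue confidence score (pLDDT, 0–100, written into
the B-factor column of the predicted model) and an N×N predicted aligned
error (PAE) matrix giving the expected positional error, in Ångström, of
residue *i* when the prediction is aligned on residue *j*. Readers of these
outputs routinely infer a protein's domain architecture from them by eye:
high-confidence stretches are structured domains, low-confidence stretches
are intrinsically disordered linkers, dark low-error squares in the PAE
matrix delineate rigid units, and dark off-diagonal patches indicate that
two domains are immobilised relative to each other by interdomain contacts.
For multi-domain families such as the human PARP family — seventeen large
proteins combining an ADP-ribosyl transferase (ART) domain with KH, RWD,
Macro, WWE, BRCT, WGR, zinc-finger and other modules — this visual reading
is productive but not reproducible: two readers will draw slightly
different boundaries, and no algorithmic record of the decision rules
exists.

`afdomains` turns that visual procedure into an explicit, parameterised,
tested pipeline, together with the quantitative satellite analyses that
accompany such annotation work: least-squares Cα core superposition against
experimental reference structures (the basis of homology labels and of the
RMSD values quoted for them) and an NMR crosspeak-intensity analysis that
classifies per-domain mobility in two states.

## The pipeline

`annotate()` chains five stages, each exposed as a function:

1. **Segmentation** (`segment_disorder()`). The pLDDT profile is smoothed
   with a running median (window 9 residues; shrinking windows at chain
   ends) and thresholded at 70, the conventional boundary between
   low-confidence and confident prediction used by the AlphaFold database
   colour scale. Structured runs shorter than `min_struct = 10` residues
   are relabelled disordered — mirroring the annotation convention of
   ignoring short isolated elements with residual secondary-structure
   propensity — and disordered gaps shorter than `min_gap = 4` sandwiched
   between structured runs are absorbed. The result provably tiles the
   chain.

2. **PAE refinement** (`refine_segments_with_pae()`). Confidence alone
   cannot separate two domains joined without a disordered linker. Each
   structured segment is therefore recursively bisected at the cut point
   maximising the block contrast of the symmetrized PAE, `gain(cut) =
   median cross-block − mean(median intra-blocks)`; a cut is accepted when
   the gain is at least `split_gain = 5` Å and both halves have at least
   `min_subsegment = 25` residues. The 5 Å default deliberately leaves
   rigid multi-subdomain arrangements (e.g. an HD–ART catalytic domain,
   cross-PAE ≈ intra-PAE) intact while cleanly separating flexibly joined
   domains, whose cross-PAE sits far above intra-domain values.

3. **Rigidity clustering** (`rigid_assemblies()`). Structured segments are
   clustered by average-linkage hierarchical clustering on the
   dissimilarity `d(A,B) = median symmetrized PAE` over residue pairs, and
   the single dendrogram is cut at two heights: `tau_domain = 5` Å groups
   segments belonging to one domain (notably the sequence-separated parts
   of a *split* domain), `tau_assembly = 10` Å groups domains into larger
   rigid assemblies. Cutting one tree guarantees that domains nest inside
   assemblies. Average linkage is used deliberately: single linkage chains
   rigid units together through the low-error band that always hugs the
   PAE diagonal. The median (not the mean) is robust both to that band and
   to individual flexible residues.

4. **Domain calls** (`call_domains()`, `detect_split_domains()`). Each
   domain-level unit becomes one call; member ranges that abut in sequence
   are merged. A call whose consecutive ranges are separated by at least
   `min_insertion = 30` residues is flagged *split* — one spatial unit
   interrupted by a long insertion, as in the split RWD and KH domains of
   several PARPs. Thirty residues separates such genuinely long insertions
   from ordinary inter-subdomain gaps; the exact part fractions are stored,
   and only the display rounds them to quarters ("¾", "¼").

5. **Contact calls** (`contact_matrix()`). Every pair of domain calls gets
   a score — the median symmetrized cross-PAE — and a boolean contact flag
   at `tau_contact = 12` Å. This is the algorithmic form of reading "darker
   patches at the intersection" of two domains, as in the rigid MZAP:ART
   arrangement that distinguishes PARP7 from PARP12.

PAE matrices are asymmetric; all comparisons use an explicit
symmetrization, by default the element-wise minimum (the more confident
direction), with the mean as an alternative. All thresholds above are in
the units of the PAE itself (Å) and are collected in `annotate_config()`.
The defaults were fixed once against the synthetic suite's planted truth
and the family's qualitative patterns; they are parameters, not constants,
and every analysis records the configuration it used in the output's
`params` attribute.

## Reference labelling and core superposition

Homology labels are attached by superposing a called domain onto a
user-supplied experimental reference (`label_by_reference()`), never by
automatic fold search. Residues are paired by global sequence alignment
(BLOSUM62, affine gaps −11/−1) unless an explicit pairing table is given
for remote homologs. The superposition engine is a standard SVD-based
Kabsch fit with determinant correction, wrapped in iterative outlier
rejection (`core_superpose()`): refit, reject pairs deviating by more than
`kappa = 2` times the current RMSD, stop at convergence, after
`max_cycles = 5`, or before the core would drop below `min_core_frac =
0.3` of the input. This emulates the refinement behaviour of interactive
"super"-style fitting in molecular viewers; because those viewers do not
publish their rejection rule, core sizes are expected to match published
values only approximately, and the package reports both the core RMSD and
the core atom count so that the comparison is explicit. The Kabsch fit is
verified in the test suite against an independent quaternion
(Horn-method) oracle on a thousand random point sets, and the
rejection loop against constructions with planted outliers.

Reproducing published RMSD anchors for real proteins (e.g. the PARP13
MZAP region against PDB 7KZH, or the PARP4 ITIHL region against PDB 6FPY)
requires the corresponding AFDB model and PDB coordinates, which are not
distributed with the package; the README lists the download commands and
the cache location the tests look in.

## Mobility from crosspeak intensities

`domain_mobility()` implements the intensity-ratio reading of two-state
TROSY spectra. Sharp, intense backbone amide crosspeaks indicate an
independently tumbling domain; incorporation into a large rigid particle
slows tumbling and broadens the signals away. Because the two spectra are
acquired separately, each state is first normalised by its own median
intensity over disordered-linker residues — flexible linkers remain sharp
in both states and act as the internal reference. The per-domain statistic
is the median (again: single unassigned or overlapped peaks must not flip
a class) of the normalised bound/free ratio; domains classify as `mobile`
(ratio ≥ 0.5), `immobilized` (≤ 0.2), `intermediate` between, or
`insufficient_data` below five assigned residues. The thresholds have no
published reference values — the source analyses are qualitative — so only
class-level reproduction is claimed, and the linker normalisation makes
the classes provably invariant under global rescaling of either spectrum.

## The synthetic generator

Because real AFDB inputs cannot be bundled, every stage is validated
against `synthetic_spec()` entries with planted, machine-readable truth:

* **Geometry**: a Cα trace with 3.8 Å virtual bonds; each domain is a
  self-avoiding walk confined to a sphere of radius 2.5·L^(1/3) Å (both
  parts of a split domain share one sphere), linkers are extended
  self-avoiding walks steered between spheres. A cornered walk restarts
  its element, with a slightly relaxed clash floor on late attempts so
  generation always terminates.
* **Confidence**: pLDDT ~ Normal(88, 3) in domains, Normal(40, 5) in
  linkers, a 3-residue linear taper across boundaries, clipped to
  [0, 100]. The domain/linker means mirror typical AFDB profiles of
  folded versus disordered regions; σ = 3 was chosen once as a realistic
  per-residue scatter.
* **PAE**: ~3 Å within a domain, ~6 Å between domains declared mutually
  rigid ("assemblies"), and a 12 + 0.05·|i−j| Å ramp for everything else,
  with independent noise for (i,j) and (j,i) — real PAE is asymmetric, so
  downstream code must symmetrize explicitly — plus the ≤ 4 Å near-diagonal
  band (|i−j| ≤ 4) always present in real matrices, without which
  change-point detection would be unrealistically easy. σ_PAE = 0.5 Å.
* **Intensities**: free-state ≈ 1 everywhere; bound-state scaled by
  U(0.05, 0.15) per immobilized domain and U(0.8, 1.0) otherwise, with
  multiplicative log-normal noise (σ = 0.1) and 10% of residues masked as
  unassigned.

All draws flow from one seeded generator per call, so identical spec and
seed give bit-identical outputs. The default study entry
(`default_synthetic_spec()`) has three domains — a 70+50-residue split
domain rigidly packed against a 110-residue partner, plus an independent
90-residue singleton — on 25–30-residue linkers, 400 residues in total:
the smallest layout that simultaneously exercises split detection,
assembly inference and contact calling. The PARP1-shaped scenario
(`parp1_like_spec()`) arranges six domains on linkers in roughly the
proportions of the 1014-residue protein, and its bound state immobilizes
everything except BRCT — the beads-on-a-string collapse.

What the generator does **not** emulate: real folds, side chains, packing
quality, pLDDT's correlation with local geometry, PAE's dependence on
actual interface size, or spectral artefacts (peak overlap, chemical
exchange). Passing the synthetic suite therefore demonstrates that the
algorithms recover the planted block structure under realistic noise — it
does not certify boundary accuracy on real proteins, where confidence
profiles can dip inside domains and PAE blocks can be ambiguous. The
external-anchor checks against experimental structures exist for exactly
that reason.

## Numerical and design choices

* Residue numbering is author numbering throughout; nothing is silently
  renumbered. Models are reduced to Cα atoms on reading because every
  downstream computation is Cα-only.
* B-factors outside [0, 100] are clipped with a warning rather than
  rejected, so experimental PDB files (real B-factors) can be read as
  references.
* A missing PAE ceiling defaults to 31.75 Å, the AFDB convention.
* Ties in clustering are broken deterministically (cluster ids renumbered
  by lowest member start); `hclust` itself is deterministic. Identical
  inputs give byte-identical SVG output.
* `core_superpose()` exits early when the RMSD reaches 1e-8 Å: at an
  exact fit the rejection rule would otherwise compare rounding noise
  against a zero threshold.
* JSON round trips write 17 significant digits so that doubles survive
  write→read bit-exactly.
* Degenerate inputs are first-class: all-disordered chains yield an
  architecture with zero domains; fewer than 3 superposition pairs, or
  collinear ones, raise a degeneracy error; fewer than 20 labelling pairs
  skip labelling with a warning.
* The package is organised as an analysis workflow — numbered drivers
  under `analysis/` reproduce the simulation, annotation, superposition,
  mobility and recovery analyses over the functions in `R/` — rather than
  as a command-line tool; the functions are the interface, and every
  driver parameter is an ordinary function argument.

## Problem sizes and benchmarks

The recovery benchmark (`recovery_benchmark()`, `analysis/05_recovery.R`)
runs the full pipeline on 50 independent 400-residue entries and scores
boundary agreement at a 5-residue slack, split-domain sensitivity,
false-split rate and contact accuracy; 50 seeds at this chain length give
150 domain and 150 pair decisions, enough to resolve the targeted rates
while keeping a full run in tens of seconds. The superposition oracle
comparison uses 1000 random point sets of 4–60 points. Under the default
noise the benchmark recovers boundaries, splits and contacts essentially
perfectly; the margins (planted contrasts of ≈ 9 Å against thresholds of
5 Å) are deliberate, since the aim is to validate the machinery, not to
trace out its failure surface — `synthetic_spec()` accepts arbitrary noise
levels for that purpose.

## Known limitations

* Boundaries inherit the smoothing window's resolution (±2–3 residues);
  published boundary estimates from visual inspection can differ by a few
  residues in either direction.
* The PAE thresholds are calibrated for AFDB-style monomer matrices;
  matrices from other predictors may need different cuts.
* Contact calls report what the matrix says; a predicted contact may
  correspond to a conformation sampled only in the presence of a ligand
  (the DNA-bound-like PARP1 matrix is the canonical example), so state
  interpretation is left to the user.
* Core-atom counts from iterative rejection depend on the rejection rule;
  agreement with viewer-derived published counts is approximate by
  construction.
* No automatic fold recognition: homology labels require user-supplied
  references and are only as good as the pairing.
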