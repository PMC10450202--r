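# afdomains

Protein domain architectures from AlphaFold2 outputs, made algorithmic.

AlphaFold2-class predictors return two things: a structural model carrying
a per-residue confidence score (pLDDT, 0–100, stored in the B-factor column)
and an N×N predicted aligned error (PAE) matrix — the expected positional
error, in Å, of residue *i* when the prediction is aligned on residue *j*.
Structural biologists read domain architectures straight off these outputs:
confident stretches are structured domains, low-confidence stretches are
disordered linkers, dark PAE squares are rigid units, and dark off-diagonal
patches betray interdomain contacts. Done by eye — as in family-wide
annotation efforts such as the recent re-annotation of the seventeen human
PARP proteins — this reading is insightful but irreproducible.

`afdomains` is for people doing that kind of annotation work. It encodes
the visual procedure as an explicit pipeline with named, recorded
parameters:

- **Segmentation** — running-median smoothing of the pLDDT profile and
  thresholding at pLDDT 70, with cleanup rules for short islands and gaps;
- **PAE refinement** — recursive change-point bisection of structured
  segments where the symmetrized PAE block contrast
  (median cross-block − mean of median intra-blocks) exceeds 5 Å;
- **Rigidity inference** — average-linkage clustering of segments on the
  median symmetrized PAE, with one dendrogram cut at τ_domain = 5 Å
  (domains) and τ_assembly = 10 Å (rigid assemblies), so domains provably
  nest inside assemblies;
- **Split-domain detection** — one spatial unit whose sequence ranges are
  separated by ≥ 30 residues is flagged split, with exact part fractions
  displayed as quarters (¾KH + ¼KH);
- **Contact calls** — median cross-PAE per domain pair, contact iff
  ≤ τ_contact = 12 Å;
- **Reference labelling** — Kabsch least-squares Cα superposition with
  iterative outlier rejection (reject pairs deviating > κ·RMSD, κ = 2, up
  to 5 cycles, core ≥ 30% of input), reporting core RMSD and core size
  against user-supplied experimental structures;
- **Mobility profiling** — per-domain median bound/free crosspeak-intensity
  ratios from two-state NMR tables, linker-normalised, classified
  mobile (≥ 0.5) / immobilized (≤ 0.2) / intermediate;
- **Rendering** — deterministic SVG architecture diagrams and annotated PAE
  heat maps (contacts dashed below the diagonal only);
- **Synthetic data** — a generator for AF2-style models, PAE matrices and
  intensity profiles with planted ground truth, so the whole pipeline is
  testable offline.

The methods vignette (`vignettes/domain-annotation.Rmd`) documents the
model, the parameters and the design decisions in detail.

## Worked example

Generate a synthetic entry (three domains: a split domain `A` rigidly
packed against `B`, plus an independent `C`), annotate it, and compare
with the planted truth:

```r
library(afdomains)

sp  <- default_synthetic_spec(seed = 1)
gen <- generate_model(sp)           # C-alpha model + ground truth
pae <- generate_pae(sp)             # planted PAE matrix

arch <- annotate(gen$model, pae)
print(arch)
#> <architecture> synthetic-default-1, 400 residues, 3 domain(s), 3 disordered region(s), 1 contact call(s)
#>   D1     unassigned   1-69 + 237-284  [split]
#>   D2     unassigned   96-204
#>   D3     unassigned   312-400

arch$contacts
#>  domain_a domain_b     score is_contact
#>        D1       D2  5.731615       TRUE
#>        D1       D3 25.583778      FALSE
#>        D2       D3 21.795065      FALSE

compare_architecture(arch, gen$truth$architecture, slack = 5)
#> <architecture_diff> agreement 100.0% (slack 5): 3/3 reference domains matched, 0 extra
#>  ref_id matched_id   jaccard max_boundary_delta agree
#>       A         D1 0.9750000                  1  TRUE
#>       B         D2 0.9909091                  1  TRUE
#>       C         D3 0.9888889                  1  TRUE
```

Reading the output: the pipeline found the planted split domain (two
sequence ranges, one spatial unit), placed every boundary within 1 residue
of the truth, and called exactly one interdomain contact — the planted
rigid pair, whose median cross-PAE (5.7 Å) sits far below the 25.6 Å of
the mobile pairs. `render_diagram(arch, "arch.svg")` draws the
corresponding architecture diagram; `write_architecture()` serialises it
as versioned JSON.

The numbered drivers under `analysis/` run the full study on synthetic
data — simulation, annotation, superposition benchmarks, the two-state
mobility analysis (beads-on-string collapse with one domain spared), and
the 50-seed recovery benchmark — writing their tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

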