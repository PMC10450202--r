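Package: afdomains
Title: Domain Architectures from AlphaFold2 Confidence and Predicted Aligned
    Error Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers protein domain architectures from the two standard
    AlphaFold2 outputs: the per-residue pLDDT confidence profile (stored in
    the B-factor column of predicted models) and the predicted aligned error
    (PAE) matrix. Provides structured/disordered segmentation of the
    confidence profile, PAE-based refinement of segment boundaries,
    clustering of structured segments into domains and rigid assemblies,
    interdomain contact calling, split-domain detection with fractional part
    labels, reference-based domain labelling via least-squares C-alpha core
    superposition with iterative outlier rejection, NMR crosspeak-intensity
    mobility profiling, and SVG rendering of architecture diagrams and
    annotated PAE maps. A synthetic-data generator produces AlphaFold-style
    models, PAE matrices and intensity profiles with planted, machine-readable
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
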