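Package: flexistab
Title: B-Factor and Consensus Guided Design of Thermostabilizing Point
    Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for designing thermostabilizing point mutations in
    enzymes from crystallographic temperature factors and homolog sequence
    consensus, together with the quantitative characterization used to
    judge such designs. Extracts per-residue C-alpha B-factors from PDB
    structures, normalizes them to z-scores, detects contiguous
    high-flexibility regions, intersects them with per-column consensus of
    a homolog multiple sequence alignment, and emits ranked candidate
    substitutions. Also fits Michaelis-Menten kinetics (Lineweaver-Burk
    and nonlinear), estimates thermal-inactivation half-lives from
    residual-activity time courses, and post-processes conformational
    ensembles (rigid superposition, per-residue RMSF, geometric
    hydrogen-bond occupancy). Seeded synthetic generators with
    ground-truth manifests cover every input kind.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
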