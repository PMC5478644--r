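Package: deamscan
Title: Structural and Sequence Analysis of AID-Mediated Cytosine Deamination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dissecting why activation-induced cytidine deaminase
    (AID) discriminates between cytosine, 5-methylcytosine and
    5-hydroxymethylcytosine in single-stranded DNA. Provides readers for
    structures and multi-model trajectories, catalytic-pocket distance
    series, substrate ring breadths with van der Waals radii, steric fit
    verdicts, protein-DNA interaction fingerprinting (van der Waals
    contacts, hydrogen bonds, pi-stacking) with per-frame occupancies,
    Kelley-penalty conformational clustering with cluster-average
    structures and superposition RMSD, an in-silico model of
    glycosylase-coupled deamination assays with gel quantification and
    relative-activity statistics, and an NNCN sequence-context pipeline
    that designs motif-tiling oligonucleotides, aligns clone reads and
    computes per-motif C-to-T deamination frequencies. Every analysis is
    exercisable on synthetic data produced by built-in generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
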