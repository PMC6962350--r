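Package: hemesite
Title: Design of Covalent c-Type Heme Attachment Sites on Structured Proteins
Version: 1.0.0
Authors@R:
    person("Hemesite", "Developers", email = "hemesite@example.org",
           role = c("aut", "cre"))
Description: Tools for engineering c-type cytochromes from structured,
    non-heme proteins such as bacterial microcompartment (BMC-H) shell
    proteins.  Mines backbone torsion angles of CxxCH heme-binding motifs
    from cytochrome structures, derives or applies Ramachandran gating
    windows, scans target structures for compatible attachment sites,
    plans the point mutations or loop insertions that create the motif,
    rigidly places an idealized c-type heme with van der Waals clash
    screening, and provides the accompanying biophysical characterization
    math: single-component Nernst redox titration fitting, Beer-Lambert
    quantitation, Henderson-Hasselbalch speciation, sequence net charge
    and isoelectric point, Soret-band spectrum normalization, and
    mass-weighted particle radius averaging.  Includes deterministic
    synthetic-data generators (ideal-geometry backbones, motif-bearing
    chains, noisy titration curves) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
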