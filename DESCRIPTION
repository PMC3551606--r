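Package: foldshift
Title: Thermodynamics of a pH-Driven Disorder-to-Order Transition in a
    Propeptide-Like Cathepsin Inhibitor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of alanine-scanning spectroscopy for a
    small propeptide-like cysteine protease inhibitor: two-state van't Hoff
    fits of circular dichroism thermal melts with derived unfolding
    thermodynamics (dH, dS, Tm, dG_u, fraction unfolded, ddG_u),
    double-mutant-cycle coupling energies, tryptophan fluorescence
    blue-shift (MEWD) quantification of the molten globule-to-ordered
    structure transition, fluorogenic protease inhibition metrics
    (initial rates, residual activity, E-64 active-site titration), and
    scanning of a conserved propeptide aromatic motif against protein
    sequences. Ships deterministic synthetic-data generators emulating the
    acquisition settings of each experiment so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
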