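Package: hairpinscape
Title: Conformational Families, Energy Landscapes and Peptide Interfaces of RNA Hairpin Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric classification of RNA hairpin conformations into
    experimentally motivated families via a pseudo-angle coordinate and
    base-triplet annotation, thermodynamic and kinetic analysis of
    minima/transition-state networks (occupation probabilities, basin
    content under an energy cutoff, harmonic transition-state-theory and
    inter-funnel rates, disconnectivity graphs), and peptide-RNA interface
    profiling (CA-phosphate distance fingerprints, gap index, Coulomb
    interaction energy, hydrogen-bond persistence).  Ships deterministic
    seeded generators for idealized hairpin conformations, planted
    mixtures, multi-funnel transition networks and docked peptide poses so
    the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
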