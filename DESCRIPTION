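Package: histofold
Title: Detection and Classification of Prokaryotic Histone-Fold Proteins
    from Predicted Structures
Version: 0.1.0
Authors@R:
    person("histofold", "developers", email = "histofold@example.org",
           role = c("aut", "cre"))
Description: Classifies archaeal, bacterial and phage histone-fold proteins
    from predicted monomer and multimer structures (PDB/mmCIF with pLDDT in
    the B-factor column, AlphaFold-style PAE matrices in JSON) and from
    sequence. Locates the alpha1-L1-alpha2-L2-alpha3 histone fold from
    C-alpha geometry, distinguishes nucleosomal from alpha3-truncated folds,
    classifies quaternary topologies (handshake dimer, face-to-face torus,
    coiled-coil bundle, C-terminal tetramerization, open stack), gates calls
    on interface predicted-aligned-error quality, annotates sequence features
    (L2 RxTxxxxD motifs, ZZ-type zinc sites, charged tails, transmembrane
    segments, conservation profiles), and assigns each protein to a histone
    category with an evidence trail. Ships a deterministic synthetic fixture
    generator producing idealized folds, oligomers, pLDDT tracks and PAE
    matrices in every supported topology, so the whole pipeline is testable
    without any structure-prediction runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
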