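Package: phycomix
Title: Identification of Homologous and Heterologous Phycobiliprotein
    Complexes from Native Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning native mass spectra of phycobiliprotein
    complexes (phycocyanin and allophycocyanin alpha-beta dimers and
    (alpha-beta)3 hexamers). Computes theoretical average masses of subunit
    proteoforms from sequence with post-translational modification rules
    (phycocyanobilin chromophores, initiator-methionine loss, asparagine
    methylation), enumerates candidate pure, heterologous and decoy complex
    compositions, deconvolves charge-state envelopes to neutral masses,
    matches them to candidates under a percent-mass-error criterion, and
    quantifies relative abundances. Also scores sequence conservation at
    structure-derived alpha-beta dimer contact interfaces (per-column
    identity and similarity, alignment-to-sequence position mapping, 3
    Angstrom heavy-atom contacts, PAE and pLDDT interface summaries), and
    includes a synthetic-data module that generates diverged strain sequence
    sets and Orbitrap-like spectra with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
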