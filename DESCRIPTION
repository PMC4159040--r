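Package: lnaclamp
Title: Design of LNA Oligonucleotide PCR Clamps That Block Plant
    Organelle SSU rRNA Gene Amplification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing locked nucleic acid (LNA)
    oligonucleotide PCR clamps that suppress amplification of plant
    organelle (mitochondrial and plastid) small-subunit rRNA genes while
    leaving bacterial 16S rRNA genes amplifiable. Provides degenerate
    primer expansion, binding-site search and coverage computation over
    sequence sets, nearest-neighbor melting temperature prediction with
    per-substitution LNA stabilization, an alignment-driven clamp design
    algorithm (conserved-window discovery, LNA placement under run and
    spacing constraints, Tm targeting, structural validation), in-silico
    PCR amplicon prediction, probe-match specificity screening, and a
    deterministic synthetic fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
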