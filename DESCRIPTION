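Package: poolsweep
Title: Simulation and Analysis of Selective Sweeps in Pooled Time-Series
    Sequencing of Evolving Microbial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward Wright-Fisher simulation of an asexual chemostat
    population with multi-allele beneficial driver genes, negative
    frequency-dependent lineages, hitchhiking mutators and neutral
    passengers; pooled-sequencing read and site-count simulation; FASTQ
    quality trimming and PCR-duplicate removal; pooled variant-calling
    filters with exact detection-probability companions; allele-frequency
    trajectory assembly with occurrence spectra, mutational load and
    gene-level summaries; and trajectory-cohort clustering with hard/soft
    selective-sweep classification. A single-config pipeline orchestrates
    all stages with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
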