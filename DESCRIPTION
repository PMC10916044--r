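Package: epickit
Title: Manifest Engineering and Cross-Platform Evaluation for Infinium
    Methylation EPICv2 Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising Infinium MethylationEPIC v2.0
    (EPICv2) BeadChip manifests and data. Parses Illumina- and
    SeSAMe-style manifests and decodes the four-character IlmnID probe
    suffix; recomputes Allele A/B bisulphite probe sequences from the
    manifest Forward_Sequence; detects exact, location and sequence-only
    replicate probes; matches probes across array generations (EPICv2,
    EPICv1, 450K, 27K) by name, location and sequence and assigns
    provenance categories; annotates probe target sites with genic,
    CpG-island and regulatory-element context; maps in-silico
    cross-hybridisation off-target sites at single-nucleotide resolution
    with a built-in small-genome aligner and a PSL reader for external
    BLAT runs; and evaluates platforms and replicate probes against a
    cross-platform consensus with row-linear sensitivity/precision fits
    and RMSE-based off-target evidence from whole-genome bisulphite
    sequencing. Seeded synthetic generators provide toy genomes, designed
    manifests, planted off-target homologies and matched multi-platform
    methylation datasets, so the whole pipeline is testable without
    external downloads. Results feed an augmented manifest CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
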