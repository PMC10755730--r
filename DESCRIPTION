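Package: deamhmc
Title: Base-Resolution 5-Hydroxymethylcytosine Calling from Deaminase
    Conversion Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for single-step deaminase
    conversion sequencing of 5-hydroxymethylcytosine (5hmC). An engineered
    APOBEC3A deaminase converts cytosine and 5-methylcytosine to bases read
    as T while sparing 5hmC, so residual C in reads marks 5hmC at base
    resolution. The package provides a deamination-aware read simulator with
    planted modification maps and spike-in controls, a minimal
    converted-genome aligner with per-cytosine strand-aware C/T counting,
    spike-in conversion-rate QC, a binomial caller for high-confidence 5hmC
    sites with Benjamini-Hochberg q-value control, genome-scale summaries
    (binned signal correlation, sequence context, feature distribution, TSS
    metaprofiles), and Michaelis-Menten deamination kinetics fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
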