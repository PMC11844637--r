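Package: ambimux
Title: Ambient-Aware Read Simulation and Variant-Consistency QC for
    Multiplexed Single-Nucleus Multiome Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotype-aware, read-level simulation of multiplexed joint
    snRNA-seq/snATAC-seq droplet experiments with per-droplet control of
    ambient RNA/DNA contamination, and a variant-consistency metric
    (C1/C2/I1/I2 allele classification against donor genotypes) for
    post-hoc estimation of residual ambient contamination in
    demultiplexed singlets. Includes self-contained synthetic reference
    generation (genome, donor VCF, region BEDs, barcode whitelist),
    droplet attribute sampling, FASTQ/BAM emission with ground truth,
    barcode-resolved allele pileups, and accuracy/concordance metrics
    for benchmarking demultiplexing methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    rtracklayer,
    clue,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'allele-pileup.R'
    'ambient-sweep.R'
    'benchmark-metrics.R'
    'cli.R'
    'droplet-sampler.R'
    'genotype-io.R'
    'read-simulator.R'
    'sim-output.R'
    'synthetic-reference.R'
    'utils.R'
    'variant-consistency.R'
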