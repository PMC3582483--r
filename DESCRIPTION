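Package: dhtrans
Title: Duplicate-Gene Detection and Full-Length Transcript Annotation for
    Doubled-Haploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-assembly analysis of de novo transcriptomes from doubled
    haploid (fully homozygous) individuals. Because a doubled haploid carries
    two identical chromosome sets, any apparent variant among reads mapped
    back to an assembled transcript is non-allelic: such pseudo-SNPs mark
    paralogous sequence variants (PSVs) between collapsed duplicated gene
    copies. The package provides read cleaning, multi-assembly merging with
    containment-based redundancy removal and N50 statistics, high-identity
    read mapping with pileup-based PSV/MSV calling under the
    zero-heterozygosity null, homology-guided and ab initio ORF prediction
    with full-length transcript classification, UTR sequence-context analyses
    (Kozak motif, stop-codon context and usage, polyadenylation-signal
    hexamer discovery), sequencing-depth saturation curves, and a
    truth-tracked synthetic doubled-haploid transcriptome and read simulator
    that makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
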