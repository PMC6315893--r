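Package: graftscope
Title: Diagnostic-SNP Genotyping and Graft-Mobile mRNA Detection
Version: 0.1.0
Authors@R:
    person("graftscope", "developers", email = "graftscope@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing two plant genotypes against a common
    reference genome and for tracing mRNA movement across graft
    junctions.  Implements post-calling SNP/InDel filters (quality,
    relative coverage, local SNP density), a lightweight variant
    consequence engine (region, codon effect, impact tier, functional
    class), two-genotype specific/common variant partitioning with
    summary statistics (zygosity, Ts/Tv, InDel length spectrum,
    per-chromosome densities), and a mobile-transcript caller that
    genotypes scion and rootstock at diagnostic SNP loci from RNA-seq
    base-count pileups and aggregates supported loci into directional
    graft-transmitting gene calls.  A seeded synthetic-data generator
    produces reference genome, gene models, genotype variant sets and
    graft RNA pileups with a known truth table so the whole pipeline is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
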