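Package: falsedup
Title: Detection and Correction of False Segmental Duplications in Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects contigs in whole-genome shotgun assemblies that are
    erroneous segmental duplications caused by the separation of the two
    haplotypes of a diploid genome. Apparent nearby duplications (duplicated
    contained contigs and duplicated overlapping contigs) are identified from
    contig-to-contig alignments, and each candidate is evaluated with a
    mate-pair placement likelihood under per-library fragment-size models that
    are re-estimated from the assembly itself when a Kolmogorov-Smirnov test
    rejects the nominal normal model. Calls are cross-checked with a Poisson
    read-coverage log-odds statistic, unplaced contigs are screened as
    haplotype variants under stricter criteria, and the SNPs and indels hidden
    in merged duplicates are recovered by re-aligning the reads of both
    haplotype contigs. Includes a fully labeled synthetic diploid assembly
    generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    BiocGenerics,
    stats,
    graphics,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
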