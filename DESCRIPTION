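Package: epscan
Title: Detection and Comparative Analysis of Exopolysaccharide
    Biosynthesis Gene Clusters in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects orthologous exopolysaccharide (eps) biosynthesis gene
    clusters across bacterial genome assemblies in the NCBI two-file
    convention (protein.faa + cds_from_genomic.fna). Ortholog calling uses
    pairwise local protein alignment with a Karlin-Altschul expectation
    screen and the MinLrap/MaxLrap alignment-length-ratio statistics; the
    cluster is reconstructed from a seed gene by genomic-context walking
    and every slot is classified (present, absent, pseudogene, fragmented,
    truncated), with insertion identification against an auxiliary query
    catalog, split detection, and synteny scoring. Cohort-level outputs
    include genes-by-genomes identity matrices, percentile summaries, a
    neighbor-joining phylogeny of concatenated cluster proteins (Poisson
    correction) and a five-gene multilocus sequence analysis phylogeny
    (Jukes-Cantor), both with bootstrap supports. A seeded synthetic-genome
    generator plants clusters subject to deletion, insertion,
    pseudogenization, fragmentation, truncation, divergence and contig
    splitting, with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: MAFFT (>= 7) for align_sequences()
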