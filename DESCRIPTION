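Package: numtscreen
Title: Haplotype Diversity Profiling and NUMT Screening for CO1 Barcode Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quality control of mitochondrial CO1 barcode data in
    population studies of the poultry red mite (Dermanyssus gallinae) and
    similar arthropods. Collapses aligned sequences into haplotypes, computes
    per-population diversity statistics (haplotype diversity Hd, segregating
    sites S, S/h), builds minimum spanning haplotype networks with a star
    expansion score, assigns haplotypes to named mitochondrial haplogroups
    (including the published cross-study synonymy), runs codon-position
    partitioned distance-tree diagnostics, and combines five warning signs
    into a per-group verdict separating functional mitochondrial lineages,
    cryptic-species candidates, and nuclear mitochondrial pseudogenes (NUMTs).
    Also phases heterozygous nuclear intron consensus sequences that carry a
    single short indel, and ships a synthetic-data generator emulating the
    demographic and molecular structure the screen assumes, so that every
    stage can be tested without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
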