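Package: strainpop
Title: Population Genomics of Strain-Level Endemism from Metagenome Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for strain-resolved population genomics of
    freshwater bacterioplankton from metagenome contigs. Reconstructs
    population genotype bins by tetranucleotide-frequency and G+C clustering
    with chimeric-contig removal, partitions population gene content into
    core, free-living-specific, and endosymbiont-specific sets by reciprocal
    best hits against reference proteomes, estimates pairwise dN/dS with
    Nei-Gojobori (1986) counting and Jukes-Cantor correction, measures codon
    usage bias with the codon deviation coefficient, and tests the coupling
    between selection strength and codon bias per gene category. Includes
    pool-based pairwise Fst, Bray-Curtis/Mantel distance-decay statistics,
    and a seeded synthetic-community generator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    mclust,
    vegan,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
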