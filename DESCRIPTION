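Package: hetrv
Title: Two-Locus Allorecognition Genetics: Invasion Simulation and
    Detection of Reproductively Isolated Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how interacting fungal allorecognition
    (heterokaryon incompatibility) loci can split a population into
    reproductively isolated groups. Provides a forward-time,
    individual-based simulator of a two-locus incompatibility system
    (het-r/het-v) under negative frequency-dependent selection and
    selfing; sliding-window population genomics (nucleotide diversity,
    Watterson's theta, Tajima's D, Hudson Fst, Dxy) with coverage-quantile
    callability masking and a permutation Fst null; linkage-disequilibrium
    decay fitting under the recombination-drift equilibrium expectation;
    clustering of mating-compatibility matrices (Gower dissimilarity,
    partitioning around medoids, silhouette and gap statistics, principal
    coordinates); strain genotyping utilities; and synthetic-data
    generators with known expectations so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
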