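Package: tyshuffle
Title: Simulation and Dosage-Based Calling of Ty1-Mediated Genome
    Rearrangements in Hybrid Yeast Diploids
Version: 1.0.0
Authors@R: person("tyshuffle", "developers", role = c("aut", "cre"),
    email = "tyshuffle@example.org")
Description: Tools for studying non-allelic homologous recombination between
    Ty1 retrotransposons in a hybrid diploid budding-yeast genome. The package
    simulates Cas9-targeted Ty-Ty recombination outcomes (deletions,
    duplications, translocations, circles, isochromosomes, inversions) and
    allelic mitotic recombination (terminal and interstitial loss of
    heterozygosity, aneuploidy) on a segmental karyotype model; synthesizes
    the per-SNP read-depth and long-read signals those events leave behind;
    calls and classifies events from SNP ratio-of-coverage profiles with
    breakpoint windows; associates breakpoints with Ty annotations and tests
    hotspot enrichment; implements cohort-level exact and goodness-of-fit
    statistics; estimates per-division event rates, including Luria-Delbruck
    fluctuation rates by the Lea-Coulson method of the median; and maps
    recombination breakpoints inside hybrid Ty elements by diagnostic-SNP
    voting across long reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
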