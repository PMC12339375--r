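Package: sketchani
Title: Coverage-Adjusted Containment ANI and Species-Level Metagenome
    Profiling from FracMinHash Sketches
Version: 0.1.0
Authors@R:
    person("Kerstin", "Moran", email = "kmoran@example.org",
           role = c("aut", "cre"))
Description: Estimates the containment average nucleotide identity (ANI)
    between reference genomes and shotgun metagenome read sets from
    FracMinHash k-mer sketches. A zero-inflated Poisson model of k-mer
    multiplicities debiases ANI estimates at low sequencing coverage, with
    bootstrap confidence intervals, effective and true coverage estimation,
    and a species-level profiler based on winner-take-all k-mer
    reassignment that reports taxonomic and sequence abundances and the
    percentage of reads detected. Includes a synthetic-data generator
    (random genomes, independent substitutions, uniform read sampling with
    errors, paired ends and PCR duplicates) used throughout the test suite,
    and a command-line interface for sketching, querying and profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
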