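Package: genarch
Title: Genomic Architecture of Population Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based analysis of the genomic architecture of population
    differentiation for multi-population resequencing data. Provides sliding-window
    population-genetic statistics (nucleotide diversity, Watterson's theta,
    Tajima's D, Dxy, Hudson's Fst, Patterson's D, fdM, haplotype-homozygosity
    tract lengths), a local-PCA/MDS scan of genome-wide structure, quartet-based
    topology weighting of window genealogies, a structured-coalescent simulator
    for three four-population isolation-with-migration topologies with optional
    intralocus recombination and a selection-aware genome-landscape generator,
    and simulation-trained dense neural networks for demographic model selection
    and parameter estimation, including selection-class-stratified estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
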