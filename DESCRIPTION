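Package: pleioscan
Title: Haplotype-Based QTL Scans, Pleiotropy Testing and Mediation for
    Microbiome and Metabolite Traits in Multiparent Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative trait locus (QTL) mapping toolchain for
    Diversity Outbred style multiparent mouse populations, applied to
    microbial abundances, metabolite (bile acid) levels and clinical
    traits.  Provides simulation of eight-founder mosaic genomes and
    kinship-structured traits with known causal architecture; trait
    preparation (prevalence filtering, taxonomic agglomeration,
    cumulative sum scaling, rank-based inverse normal and log2
    transforms, internal-standard normalization); linear mixed model
    genome scans on founder haplotype dosages with leave-one-chromosome-
    out kinship, pooled permutation thresholds, Bayes credible support
    intervals and founder allele effects; detection of co-mapping
    microbe-metabolite QTL pairs; a pleiotropy-versus-two-loci
    likelihood ratio test with parametric bootstrap; mediation analysis
    by LOD drop with causal model selection; and deterministic assay
    calculations (growth rate, percent bile-acid conversion, relative
    expression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
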