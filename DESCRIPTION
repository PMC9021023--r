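Package: cryptclock
Title: Somatic Mutation Burden, Signatures and Lifespan Scaling from
    Colorectal Crypt Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative somatic-mutation analysis of
    clonal tissue units (colorectal crypts) across mammalian species: a
    synthetic multi-species cohort generator with full ground truth; a
    post-calling variant filter stack including the beta-binomial
    cross-sample overdispersion filter; truncated binomial mixture modelling
    of VAF distributions for crypt clonality assessment; genome-corrected
    mutation burden, per-year rate and end-of-lifespan burden estimation
    (nuclear and mitochondrial); maximum-likelihood mutational-signature
    fitting and extraction on trinucleotide spectra with mutational
    opportunities; allele-specific copy-number screening from binned
    coverage and SNP B-allele fractions; and cross-species comparative
    regressions (heteroscedastic linear mixed-effects models, zero-intercept
    inverse-lifespan scaling, allometric and partial-correlation analyses,
    bootstrap and phylogenetic generalized least squares).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    flexsurv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
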