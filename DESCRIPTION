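Package: ltgmap
Title: Genetic Dissection of Seed Low-Temperature Germinability with
    Substitution Lines and Bulked-Segregant Sequencing
Version: 0.1.0
Authors@R:
    person("ltgmap", "developers", email = "ltgmap@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting quantitative trait loci (QTLs) of seed
    low-temperature germinability in rice using single segment substitution
    line (SSSL) libraries.  Provides per-line QTL detection by Student's t
    tests on arcsine-transformed germination proportions, additive-effect
    and contribution estimation, broad-sense heritability from variance
    components, substitution mapping by interval intersection and
    negative-evidence subtraction, F2 segregation and additive/dominance
    genetics via coded single-marker regression, recombinant-progeny fine
    mapping, bulked-segregant delta SNP-index analysis with simulated
    confidence bands and candidate-interval calling, a candidate-gene
    filter cascade (annotation, variant impact, seed expression), and a
    forward simulator producing SSSL libraries, F2 populations and pooled
    sequencing depths with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
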