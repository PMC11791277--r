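Package: mutascope
Title: Simulation and Detection of dNTP-Imbalance-Driven CG>TA Mutagenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline linking deoxynucleotide (dNTP) pool
    imbalance to CG>TA transition mutagenesis and its detection. Provides an
    error-prone PCR simulator under unequal dNTP pools with a strand-alternating
    dG:dT mispair model, mutation-spectrum and hotspot-codon analysis of
    amplicon reads (4x4 substitution matrices, per-site frequencies,
    base-composition and A+T-enrichment summaries), melting-temperature
    estimation and melting-curve synthesis for hydrogen-bond-loss mutant
    screening, denaturation-gradient (3D-PCR-style) selection of AT-rich
    alleles, codon-level variant-consequence annotation with RAS hotspot and
    transforming-residue rules, free-energy-change (ddG) stability
    classification, and cohort-level screening (mutation prevalence, paired
    tumor/healthy Tm permutation tests, delta-delta-Ct fold changes). All
    inputs can be generated synthetically with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
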