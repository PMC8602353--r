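Package: codonbias
Title: Codon Usage Bias Analysis of Orthologous Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of synonymous codon usage bias across cohorts of
    orthologous protein-coding sequences. Computes relative synonymous codon
    usage (RSCU) with over/under-representation classification and a
    cross-species dispersion statistic, the effective number of codons (ENC)
    with the GC3 null-curve diagnostic, parity rule 2 (PR2) bias coordinates,
    six nucleotide skew variants with overall-versus-positional correlation
    analysis, Shannon entropy measures of positional nucleotide composition,
    and principal component analysis of codon and amino-acid usage. Includes
    a synthetic coding-sequence cohort generator with mutation-pressure and
    selection bias models for method validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
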