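Package: purisel
Title: Purifying-Selection Contrasts Between Sexual and Asexual Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the effectiveness of purifying selection
    between reproductive modes across a fixed species phylogeny. Implements
    a Muse-Gaut (MG94) style codon substitution model with per-branch
    free-ratio dN/dS estimation by maximum likelihood, marginal ancestral
    codon reconstruction, hydrophobicity-based scoring of amino-acid
    replacements on terminal branches, codon-usage-bias statistics
    (Wright's effective number of codons and the codon deviation
    coefficient), and permutation/rank-based comparisons between sexual
    and asexual lineages. A codon-level sequence simulator generates
    study-shaped datasets (paired sexual/asexual taxa across groups plus
    an outgroup) under purifying selection with codon-usage bias, with an
    optional elevation of dN/dS on asexual terminal branches, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
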