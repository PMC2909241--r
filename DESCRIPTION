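Package: pkinv
Title: Inverse Folding of 3-Noncrossing RNA Pseudoknot Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design of RNA sequences folding into target structures with
    cross-serial base pairs (pseudoknots). Implements the diagram model of
    k-noncrossing, sigma-canonical structures with readers and writers for
    extended dot-bracket, bpseq and CT formats; the unique loop
    decomposition into hairpin, interior, multi- and pseudoknot loops;
    compatible-sequence space utilities (uniform compatible sampling,
    u-/p-neighborhoods, compatible distance); an exhaustive reference
    folding oracle under an additive loop-based energy model; and a
    stochastic local search for inverse folding driven by
    perturbation-derived competitor structures and the interval sequence of
    the loop decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    seqinr,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
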