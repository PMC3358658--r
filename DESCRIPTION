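Package: kisbubble
Title: Reference-Free Detection of Transcriptome Polymorphisms as Bubbles in a
    Bidirected De Bruijn Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies transcriptome polymorphisms (alternative
    splicing events, SNPs, short indels and approximate tandem repeats) directly
    from RNA-seq reads, with no reference genome. Reads are decomposed into
    k-mers, assembled into a bidirected compressed De Bruijn graph, and
    polymorphisms are recovered as "bubbles": simple cycles with exactly two
    switching nodes. The package implements biconnected-component
    decomposition, four-node (substitution) bubble compression, pruned
    backtracking bubble enumeration, path alignment and event classification,
    read-coherence filtering with border-corrected per-path coverage, and a
    read simulator for sensitivity studies with planted events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
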