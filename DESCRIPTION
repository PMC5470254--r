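Package: redipr
Title: Rediploidization Dynamics and Ohnologue Divergence After Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how duplicated genomes return to a diploid state
    after whole-genome duplication, modelled on the salmonid fourth-round
    (Ss4R) autotetraploidization. Classifies gene trees as showing ancestral
    (AORe) or lineage-specific (LORe) ohnologue resolution using a
    species-overlap duplication criterion, maps rediploidization events onto a
    dated species tree, segments chromosomes into LORe/AORe blocks and
    extrapolates genome-wide ohnologue counts and per-lineage rediploidization
    rates. Quantifies regulatory divergence of ohnologue pairs from RNA-seq
    counts (TMM-normalized counts per million, tissue-profile and
    condition-response Pearson correlations, Wilcoxon group contrasts,
    regulatory-neofunctionalization calls and hypergeometric enrichment) and
    contrasts gene-function composition of LORe versus AORe gene sets with
    filtered Fisher tests and a physical clustering index. A seeded synthetic
    data generator produces gene trees, genome layouts and expression matrices
    with known truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    withr
Config/testthat/edition: 3
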