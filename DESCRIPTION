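Package: exomesieve
Title: Annotation, Filtering and Cohort Analysis of Exome Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline toolkit for prioritising candidate disease-related
    variants from exome sequencing call sets. Parses SNV and InDel calls from
    VCF, samtools consensus-pileup and SOAPsnp tabular files; classifies each
    variant against UCSC refGene-style gene models into functional categories
    (missense, nonsense, read-through, synonymous-coding, splice site, UTR,
    intronic, intergenic for SNVs; frame-shift, in-frame amino-acid
    insertion/deletion, non-coding for InDels); flags novelty against a
    known-variant catalogue with a clinically-associated flag; tests sample
    allele frequencies against population panels (YRI/JPT/CHB/CEU style) with
    a chi-square test; and applies declarative filter criteria plus two-case,
    multiple-case and trio Mendelian cohort analyses. Includes a deterministic
    synthetic-fixture generator that emits genomes, gene models, variant files,
    catalogues and panels with complete truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
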