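Package: transpop
Title: Reference-Free Transcriptome Variant Discovery and Comparative
    Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise SNP and indel discovery from transcriptome read
    alignments for species without a reference genome, using a strict
    depth and consensus-fraction calling rule with self-comparison
    artifact filtering and non-redundant consolidation per reference
    transcript set.  Discovered variants are anchored onto the
    pseudomolecules of two related species via transcript-to-genome
    mappings ("virtual chromosomes") and integrated across the two
    anchor sets.  Includes a high-confidence cross-species SNP matrix
    builder and population-genetic summaries (segregating sites,
    Watterson's theta, nucleotide diversity, Tajima's D, fixed
    differences, outgroup-polarized site-frequency spectra,
    neighbor-joining trees with bootstrap support), reciprocal-best-hit
    orthology, FPKM expression quantification, indel PCR marker
    selection, and a fully seeded synthetic-data generator with truth
    tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
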