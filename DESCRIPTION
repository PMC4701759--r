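Package: wophage
Title: Spectral-Counting Proteomics of Wolbachia WO Prophage Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free spectral-counting analysis of the WO prophage
    proteome expressed by arthropod-associated Wolbachia. Provides in-silico
    tryptic digestion, exact-substring peptide-to-protein matching across
    homolog databases, sequence-coverage computation, stringent and relaxed
    detection filters, refined-search augmentation of the search database,
    relative abundance level (RAL) scoring, mass-normalized abundance via
    externally studentized residuals of a log-log peptide-count regression,
    prophage-region classification with module-by-class tallies, pairwise and
    concatenated percent-identity comparison of syntenic gene arrays,
    intergenic layout and direct-repeat detection, and a synthetic-data
    generator that emulates multi-data-set mass-spectrometry detection for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
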