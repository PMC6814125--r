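Package: rootmir
Title: Water-Deficit miRNA, IsomiR, Degradome-Target and Target-Mimic
    Analysis for the Maize Primary-Root Growth Zone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a small-RNA inference chain for
    water-deficit-responsive microRNAs in the maize primary-root growth zone:
    adapter trimming and quality filtering of small-RNA and degradome (PARE)
    reads, unique-tag collapsing, assignment of tags to canonical miRNAs and
    isomiR classes, RPTM normalization with a retention filter, TMM-normalized
    negative-binomial differential-abundance testing with Benjamini-Hochberg
    correction and replicate quality control, degradome cleavage-site target
    validation (at least one read at miRNA positions 9-11, fewer than 4
    mismatches), detection of miR399-style target mimics (eTMs) with a central
    bulge at the cleavage site, coherence classification of miRNA-target pairs,
    and stem-loop RT-qPCR ddCt relative quantification. A synthetic-data
    generator with ground-truth labels emulates the study design (three
    watering treatments, four replicates) so the whole chain is exercised
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    edgeR,
    limma,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
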