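Package: twinmeth
Title: Twin-Discordant Methylome-Transcriptome Integration for Infant Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integration analysis of 450K-array DNA methylation and gene
    expression for KMT2A/AFF1-rearranged infant acute lymphoblastic leukemia
    studied through a discordant monozygotic twin design. Implements the
    twin-contrast delta-beta filter, paired diagnosis-remission replication by
    t-test, probe-to-gene promoter annotation, paired differential expression
    on normalized counts with Benjamini-Hochberg FDR control, CpG-gene Pearson
    correlation signature selection, and structural quality control (Euclidean
    distance clustering, targeted PCA with reference cell profiles, parental
    comparability). Ships a synthetic-data generator with known ground truth
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
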