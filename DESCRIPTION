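Package: topovote
Title: Topological, Local and Hybrid Voting for Segmentation Mask Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses ensembles of co-registered binary (hard) or continuous
    (soft) segmentation masks of one image by voting. Implements per-pixel
    arithmetical voting (majority, averaging, weighted averaging), global
    topological "winner takes all" voting under the Jaccard distance, local
    topological voting on sliding square neighborhoods, and two-round hybrid
    voting in which topological scoring excludes outlier annotators before an
    arithmetical second round. Includes the hard and soft (min-over-max)
    Jaccard machinery, a seeded generator of synthetic truth masks and
    annotator ensembles with structured outliers, and one- and two-dimensional
    estimator simulations comparing the sample-average estimator with the
    medoid-style topological estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
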