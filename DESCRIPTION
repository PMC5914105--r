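Package: qamsfp
Title: HPLC Fingerprint Similarity, Clustering and Single-Marker (QAMS)
    Quantification for Fermented Cordyceps Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality evaluation of fermented Cordyceps sinensis products
    (Jinshuibao capsules and tablets, Bailing capsules) from HPLC-UV
    chromatograms of the five marker nucleosides (uracil, uridine, adenine,
    guanosine, adenosine). Implements chromatogram simulation with known
    ground truth, peak detection and chord-baseline integration, common-peak
    matching with relative retention times and peak areas, retention-time
    normalization, mean-reference fingerprint similarity (cosine and
    Pearson), hierarchical cluster analysis with cosine distance and
    between-groups (average) linkage, linear calibration with
    signal-to-noise based detection and quantification limits, external
    standard quantification, and quantitative analysis of multicomponents
    by single marker (QAMS) via relative correction factors, including
    robustness summaries and vector-angle agreement between QAMS and the
    external standard method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
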