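Package: fiberform
Title: Proteoform-Resolved Top-Down LC-MS Analysis of Single Muscle Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: MS1-level top-down proteomics of single skeletal muscle fibers:
    simulation of QTOF LC-MS runs of co-eluting fast/slow sarcomeric
    proteoforms with ground-truth manifests, mzML input/output, retention-time
    spectrum averaging, extracted ion chromatograms with area-under-curve
    integration, charge-state envelope deconvolution and isotopically resolved
    (SNAP-style) monoisotopic mass determination, averagine isotopic-pattern
    fit validation, proteoform assignment by accurate mass with modification
    and unexplained-shift reporting, and per-fiber quantification of isoform
    ratios, proteoform relative abundance, and site-weighted phosphorylation
    stoichiometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
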