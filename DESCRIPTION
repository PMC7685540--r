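Package: spineshare
Title: Intervertebral Motion Sharing Biomarkers from Quantitative
    Fluoroscopy and Their Investigator Repeatability
Version: 0.1.0
Authors@R:
    person("Spineshare", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing passive recumbent lumbar
    flexion examinations of the kind acquired with quantitative
    fluoroscopy (QF).  The package generates ground-truth intervertebral
    kinematics for the four lumbar levels L2-L3 to L5-S1 under a
    motorised-table motion profile, optionally renders synthetic image
    sequences and tracks vertebral bodies through them by normalized
    cross-correlation template matching, computes the motion sharing
    biomarkers MSI (Motion Sharing Inequality) and MSV (Motion Sharing
    Variability) from proportional intervertebral rotations, and
    estimates intra- and inter-investigator repeatability via
    two-way random-effects intraclass correlation (ICC(2,1)), standard
    error of measurement (SEM) and minimal difference (MD).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
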