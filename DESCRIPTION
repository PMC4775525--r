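Package: ngsterr
Title: Territoriality and Home-Range Inference from Noninvasive Genetic Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sex-specific home-range size differences and intrasexual
    territoriality from the spatial configuration of genotyped scat samples.
    Provides genotype quality control for multitube microsatellite data
    (replicate consensus, quality index, probability of identity, individual
    matching), kernel utilization distributions with percent-volume contours
    and minimum convex polygons, a use-availability resource-selection design
    contrasting neighbor locations before and after a focal individual's
    death, logistic mixed models with hierarchical candidate-model selection,
    and a synthetic-data generator emulating territorial scat-sampling data so
    that every stage of the pipeline can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    splines,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
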