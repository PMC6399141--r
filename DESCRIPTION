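Package: tankecgi
Title: Torso-Tank Electrocardiographic Imaging Validation with Optical Mapping
Version: 0.1.0
Authors@R: person("Tank", "ECGI Maintainers", email = "maintainers@tankecgi.org", role = c("aut", "cre"))
Description: A synthetic torso-tank platform for validating electrocardiographic
    imaging (ECGI) against optical mapping. Generates heart-in-tank geometry,
    propagating activation and repolarization fields, unipolar electrograms,
    tank surface potentials and voltage-sensitive-dye movies; aligns the 3D
    geometry to the 2D optical window by two-stage camera optimization;
    reconstructs epicardial electrograms from tank potentials by the method of
    fundamental solutions with Tikhonov regularization and CRESO parameter
    selection; detects activation and repolarization markers; and quantifies
    map agreement with nearest-pixel pairing, Pearson correlation, RMSE,
    gradient profiles and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
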