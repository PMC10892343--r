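Package: frtkit
Title: Automated Functional Reach Test Measurement from Wearable MARG Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the Functional Reach Test (FRT) distance and the
    associated fall-risk class from body-worn magnetic, angular-rate and
    gravity (MARG) sensor recordings. Device orientation is estimated by
    quaternion gradient-descent sensor fusion (Madgwick-type), Earth-frame
    linear acceleration is recovered and double-integrated to position with
    high-pass drift filtering, and the reach distance is extracted as the
    extent of the movement along its principal horizontal direction.
    Includes spline resampling of jittered sensor timestamps, FIR gravity
    removal, movement-window segmentation, error metrics and orientation
    benchmarking, reference norm lookup, a ten-file CSV assessment reader
    and writer, and a synthetic MARG trial simulator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
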