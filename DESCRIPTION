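Package: helixreg
Title: Single-Pose CBCT Image-to-Robot Registration for Histotripsy Guidance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a single-pose image-to-robot registration workflow for
    cone beam CT (CBCT) guided robotic histotripsy. A helical fiducial phantom
    attached to the robot arm is imaged once; fiducials are segmented from the
    CBCT volume by percentile thresholding and connected-component analysis,
    matched to a digital phantom model through a distance-pattern
    correspondence, and the phantom-to-CBCT transform is estimated by affine
    least squares followed by rigid direct-search refinement. The package also
    provides the targeting-pose computation that aligns the transducer focal
    point on a CBCT target, synthetic CBCT rendering of the fiducial phantom
    and of multi-layered agar treatment phantoms, treatment-zone segmentation
    with target registration error measurement, and the reproducibility
    statistics (pooled summaries, Student t-tests, day-centered variance
    F-tests, Benjamini-Hochberg correction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
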