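Package: thermoface
Title: Automated Face Detection, Landmark Tracking and Analysis in Thermal
    Infrared Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular pipeline for fully automated analysis of human faces in
    long-wave infrared (thermal) image sequences: HOG-SVM sliding-window face
    detection with hard-negative mining, a 68-point statistical shape model
    (generalized Procrustes analysis plus a PCA parameter layer), active
    appearance model fitting and a PCA-constrained cascaded shape regressor,
    piecewise-affine face frontalization over a shared Delaunay triangulation,
    and two analysis heads: contactless respiratory signal extraction from a
    nostril region of interest (with rate and apnoea estimation) and four-class
    facial emotion recognition (HOG features plus a random forest). Includes a
    synthetic thermal-face generator producing images and videos with exact
    ground-truth landmarks, head motion, breathing modulation and emotion
    labels, so every stage can be trained and evaluated without proprietary
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    e1071,
    jsonlite,
    png,
    ranger,
    graphics,
    grDevices,
    stats,
    tools,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
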