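Package: cagepose
Title: Lying-Posture Detection for Caged Broilers from RGB-D Imagery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classical computer-vision pipeline that detects lying broilers
    in caged housing from registered color and depth images. The feeding
    trough occludes a standing bird's body, so a lying bird is the only
    large obstruction in the strip of image directly beneath the trough.
    The pipeline deskews the camera roll from the trough's edge lines
    (Sobel + double Hough transform), locates the trough in the depth
    image (row-variance or keypoint-sparsity method), derives the key
    area beneath it, and segments lying birds by a per-column dynamic
    depth threshold followed by morphological and geometric filtering.
    Includes a merged 16-bit 4-channel RGB-D PNG codec, a synthetic cage
    scene generator with ground-truth annotations, and an evaluation and
    parameter-tuning harness (IoU matching, precision/recall/F1, grid
    search, daily lying-time status rule).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
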