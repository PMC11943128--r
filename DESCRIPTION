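Package: annomask
Title: Turn Expert Contour Annotations on Medical Images into Segmentation Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Converts expert-drawn green contour markings on MR slices into
    paired image crops and binary ground-truth masks for supervised
    segmentation. The marked image is thresholded in HSV colour space, contour
    interiors are filled by a morphological chain (fill, close, fill, erode),
    annotated regions are located as connected components, bounding boxes are
    expanded and deduplicated by a proximity rule, and matched crops are cut
    from the marked and raw slices. Includes a training-dataset assembler
    (seeded train/validation split and rotation augmentation), a
    semantic-segmentation metric suite (pixel confusion matrix, global and
    mean accuracy, per-class, mean and frequency-weighted IoU,
    column-normalised rates, boundary-F1 score), and a synthetic phantom
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
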