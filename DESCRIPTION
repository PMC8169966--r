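Package: ocunet
Title: Octave-Convolution Encoder-Decoder Networks for CT Tumor Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the octave convolution operator (multifrequency
    feature maps one octave apart in spatial resolution), an encoder-decoder
    segmentation network (OCunet) with transpose-convolution decoding, deep
    supervision and a soft Dice objective, together with voxel-wise
    segmentation metrics (precision, recall, accuracy, specificity, Dice),
    NIfTI volume input/output with intensity windowing, and a synthetic
    CT-phantom generator so the full train/predict/evaluate pipeline can be
    exercised and tested on a single CPU without clinical data. All
    convolution forward and backward passes are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
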