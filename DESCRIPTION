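Package: tumormorph
Title: Morphological Segmentation of Hyperintense Brain Tumors in MRI Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic segmentation of hyperintense brain tumors on
    single 2D magnetic resonance slices (T1c, T2 and FSPGR T1c; axial,
    coronal or sagittal) using classical morphology: histogram equalization,
    h-maxima suppression by grayscale reconstruction, regional-maxima
    binarization, skull and meninges exclusion by brain-edge coordinates,
    suppression of non-tumor components by mean-area filtering, and
    morphological post-processing (dilation, hole filling, masking).
    Includes hit-rate and matching-rate evaluation against gold-standard
    masks, a seeded synthetic head-phantom generator for testing without
    patient data, reading of single-frame DICOM and PNG/TIFF slices, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
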