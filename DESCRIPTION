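Package: petseg
Title: Texture-Feature Region Growing for PET Tumor Volume Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic delineation of FDG-PET lesions by a 3D region-growing
    algorithm whose stop criterion is a threshold on a textural feature
    (intensity kurtosis, co-occurrence-matrix local entropy, or size-zone-matrix
    long-zone emphasis), together with the classical 40%-of-maximum adaptive
    threshold method as a reference. Includes a synthetic moving-sphere phantom
    generator (partial-volume rasterization, Gaussian point-spread blurring,
    signal-dependent noise, sinusoidal respiratory motion) and repeated-measurement
    stability statistics (mean, range, absolute and relative standard deviation)
    for comparing segmentation methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
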