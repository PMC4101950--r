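Package: pelvicut
Title: Planning and Accuracy Evaluation of Guided Pelvic Bone Tumor Resections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for computer-assisted planning and quantitative evaluation
    of guided bone tumor resections on triangle meshes. Plans target cutting
    planes at a surgeon-chosen safe margin around a tumor model, simulates
    guided cuts on synthetic bone phantoms (placement noise, saw kerf,
    post-operative scan displacement and jitter), rigidly registers the
    post-operative model back to the pre-operative frame with trimmed
    iterative closest point, extracts achieved cut planes, and computes the
    achieved surgical margin (SM), the error in safe margin (ESM), the
    ISO1101-style location accuracy (L), UICC margin classes and t-based
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
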