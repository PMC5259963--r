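Package: trabecula
Title: Morphometry and Biomechanics of the Aqueous Humor Outflow Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the conventional aqueous humor outflow
    pathway from optical-section image stacks. Provides a calibrated synthetic
    generator of two-photon limbus scenes with voxel ground-truth labels;
    depth-resolved trabecular meshwork porosity estimation by gray-histogram
    (Otsu) threshold segmentation; Schlemm's canal and aqueous vein diameter
    profiling by lumen detection and repeated centroid-chord averaging;
    voxel-based reconstruction of segmented tissue into a conforming linear
    tetrahedral mesh; and a small-strain linear-elastic finite-element solver
    for trabecular meshwork deformation under the pressure drop between
    intraocular and episcleral venous pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
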