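Package: wormAlign
Title: Canonicalization, Atlas Construction and Generalized-Mean Alignment of C. elegans Neuron Point Clouds
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated identification of Caenorhabditis elegans
    neurons in 3D fluorescence-derived point clouds. The package
    straightens arbitrarily bent worms into a canonical coordinate frame
    using a chain of inscribed tangent circles fitted to the 2D body
    hull, builds statistical positional atlases (componentwise median
    and median-absolute-deviation spread) from multiple canonicalized
    worms, and matches unlabeled neurons to an atlas with a
    generalized-mean (power-mean) alignment loss minimized by gradient
    descent, optionally parameterized through a biologically realistic
    Gaussian-mixture deformation field. Includes greedy color-constrained
    identity assignment, simulation generators for rigid jitter,
    cropping, dropout, deformation noise and randomized color codes, a
    synthetic bent-worm fixture generator with analytic ground truth,
    and a benchmarking harness for accuracy-versus-perturbation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tiff,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'pointcloud.R'
    'io.R'
    'atlas.R'
    'gm-align.R'
    'perturb.R'
    'synthworm.R'
    'benchmark.R'
    'canonicalize.R'
    'wormAlign-package.R'
    'zzz.R'
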