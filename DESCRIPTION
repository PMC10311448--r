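Package: gaussrf
Title: Generalised Gaussian Derivative Models of Visual Receptive Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs the generalised Gaussian derivative models of visual
    receptive fields used to describe simple cells in the primary visual
    cortex and neurons in the lateral geniculate nucleus: affine Gaussian
    kernels with scale-normalised directional derivatives over the spatial
    domain, the time-causal limit kernel (a cascade of first-order temporal
    integrators with geometrically distributed time constants) over the
    temporal domain, and velocity-adapted spatio-temporal receptive fields
    over joint space-time. Implements the natural image transformations
    (spatial affine and scaling transformations, Galilean transformations,
    temporal scalings) these receptive-field families are covariant under,
    the parameter-matching laws that realise the covariances, and a numerical
    verification suite that measures filter-then-warp versus warp-then-filter
    residuals for each commutative diagram, including negative controls.
    Also provides population generators over the transformation groups and
    the receptive-field shape statistics (eccentricity, speed, scale)
    proposed for testing hypotheses about biological receptive-field
    variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
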