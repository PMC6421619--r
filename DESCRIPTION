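Package: cartregen
Title: Reaction-Diffusion Simulation of Cartilage Regeneration After Cell Implantation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the healing of a chondral defect after implantation of
    mesenchymal stem cells, using a one-dimensional six-field reaction-diffusion
    model of stem cells, chondrocytes, extracellular matrix, nutrient, and the
    growth factors FGF-1 and BMP-2. Provides the dimensional and dimensionless
    parameter sets with non-dimensionalisation, a second-order method-of-lines
    discretisation integrated with stiff solvers from 'deSolve', named
    growth-factor scenarios and one-at-a-time parameter sweeps, and summary
    metrics (spatial means, percent differences between scenarios, front
    positions, defect fill time) together with CSV/JSON result export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
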