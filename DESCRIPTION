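Package: ovocflux
Title: Biosphere-Atmosphere Exchange of Isoprene Oxidation Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the deposition of the isoprene photooxidation
    products 1,2-ISOPOOH and methyl vinyl ketone (MVK) into plant leaves,
    their in-leaf conversion to methyl ethyl ketone (MEK), and the
    re-emission of MEK to the atmosphere. Provides enclosure mass-balance
    estimation of exchange fluxes, deposition velocities and conversion
    yields; a mechanistic two-compartment leaf uptake-conversion box model
    with Henry's-law partitioning, Fenton-type hydroperoxide decomposition
    and Michaelis-Menten enzyme kinetics; a resistance-in-series (Wesely)
    dry-deposition calculator; eddy-covariance flux processing with lag
    correction and despiking; global molar MEK budget accounting; and
    synthetic-data generators with known ground truth for every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
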