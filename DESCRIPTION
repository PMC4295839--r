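Package: promkin
Title: Quantitative Promoter Regulation Models from Reporter Gene Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers quantitative models of bacterial promoter regulation from
    time-series fluorescent reporter data acquired in microplate experiments.
    Derives promoter activities and reporter concentrations from absorbance
    and fluorescence signals with smoothing splines, reconstructs regulator
    protein concentrations under stated half-lives by integrating a kinetic
    model of gene expression, corrects for global physiological effects using
    a constitutive promoter, fits mechanistic titration/Hill regulation
    functions by weighted multistart optimisation with bootstrap confidence
    intervals, infers minimal sign patterns of regulatory interactions, and
    provides simulation studies quantifying when protein kinetics and global
    effects matter. Includes a forward simulator of microplate reporter
    datasets emulating the FliA-FlgM module of the E. coli motility network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    lhs,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
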