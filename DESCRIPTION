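Package: medlv
Title: Mechanistic and Lotka-Volterra Pairwise Models of Chemically
    Mediated Microbial Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking when Lotka-Volterra pairwise models can and
    cannot represent microbial interactions mediated by diffusible
    chemicals.  Provides mechanistic ordinary-differential-equation
    simulators that track species densities together with mediator
    concentrations (reusable or consumable, with turbidostat-style
    dilution events and extinction handling), the family of pairwise
    model forms (linear, logistic, saturable, the divided-influence
    "alternative" form, and a competitive-commensal hybrid), closed-form
    regime classification and convergence theory for communities coupled
    by a single consumable mediator, a staged nonlinear-least-squares
    pipeline that fits pairwise parameters to mechanistic reference
    dynamics and scores out-of-window predictions with a log10
    fold-difference metric, and scenario presets with declared
    qualitative expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
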