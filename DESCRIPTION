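Package: copepodFR
Title: Functional Response and Predation Efficiency Analysis for Copepod
    Predators of Mosquito Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing laboratory predation trials in which
    cyclopoid copepods (e.g. Macrocyclops albidus, Megacyclops viridis)
    prey on newly-hatched mosquito larvae.  Implements response-type
    classification (type II vs type III) from polynomial logistic
    regressions, maximum-likelihood estimation of attack coefficient,
    handling time and background prey mortality around the prey-depletion
    differential equation (with the Rogers random-predator closed form as
    a fast path), profile-likelihood confidence intervals,
    Abbott-corrected predation efficiency with linear-model selection,
    allometric length-to-mass conversion and body-size comparisons, and a
    seeded synthetic-trial generator (binomial and Gillespie modes)
    reproducing the experimental design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
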