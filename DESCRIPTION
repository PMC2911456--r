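Package: srbdyn
Title: Spatial Rule-Based Simulation of Diffusing, Geometrically
    Constrained Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained, particle-based spatial simulator for rule-based
    reaction systems. Diffusing spherical elementary molecules carry named
    components placed by polar coordinates; components bind, unbind and change
    modification states according to BioNetGen-language reaction rules, and
    reactions fire only between pattern-matched, geometrically compatible
    partners. Movement follows Langevin dynamics with harmonic bond and angle
    forces and soft-sphere volume exclusion; monomolecular events run through a
    fragmented Gillespie algorithm. Ships generators for four example systems
    (scaffold-protein signalling, microtubule growth with molecular walkers,
    spheric self-assembly, DNA-tile Sierpinski triangles) plus trajectory and
    structure analysis tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
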