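Package: dnaspool
Title: Spiral Genome Tracing and All-Atom DNA Model Building for
    dsDNA Virus Density Maps
Version: 0.1.0
Authors@R:
    person("dnaspool", "developers", email = "dnaspool@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing spooled double-stranded DNA genomes in
    cryo-EM density maps of icosahedral viruses. Generates coarse-grained
    pseudoatom traces following idealized spherical or cylindrical spirals
    (including multi-start families and harmonic radius modulation), scores
    them against MRC/CCP4 density grids with a summed fitting energy,
    scans and optimizes spiral parameters by coordinate descent, detects
    concentric winding shells from energy-versus-radius curves, upgrades
    optimal traces to all-atom B-form DNA duplexes by rigid-body placement
    of an idealized base-pair template, and evaluates analytic capsid
    geometry rules that quantize capsid inner diameters in the number of
    points of entry and of winding shells. Includes a synthetic-map
    generator (Gaussian-splatted planted spirals) for validation and a
    command-line interface for end-to-end workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
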