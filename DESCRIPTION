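Package: fabdyn
Title: Fab and Fc Conformational Dynamics Analysis for Antibody Trajectories
Version: 0.1.0
Authors@R:
    person("fabdyn", "developers", email = "fabdyn@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for IgG conformational dynamics from molecular
    dynamics trajectories. Computes Fc-anchored spherical orientation angles
    (theta/phi) of the Fab arms, reweights accelerated-MD ensembles to a
    two-dimensional free-energy surface via a truncated Maclaurin expansion of
    the boost-energy exponential, extracts minimum-energy frames, clusters them
    with the GROMOS (Daura) algorithm, and characterises the selected
    conformers with contact counts, hydrogen bonds, DSSP-style secondary
    structure, Shrake-Rupley solvent-accessible surface area, surface patches,
    and dynamic cross-correlation maps. A two-sample statistics layer (Student
    t, Cohen's d with confidence interval) compares antibody forms, and a
    seed-deterministic synthetic-trajectory generator provides ground-truth
    systems for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
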