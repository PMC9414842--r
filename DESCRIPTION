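Package: liporsc
Title: Random Spherically Constrained Cryo-EM Analysis of Membrane Proteins in Liposomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for random spherically constrained
    (RSC) single-particle cryo-EM of membrane proteins reconstituted into
    liposomes. Generates synthetic proteoliposome micrographs with a
    spherical-bilayer membrane model and a tetrameric channel phantom; detects,
    fits and subtracts the liposome membrane contribution under the contrast
    transfer function; picks and distance-screens particles; converts liposome
    geometry into orientation priors (membrane-normal tilt from the particle's
    radial offset on the vesicle sphere); reconstructs 3D maps by direct
    Fourier inversion under C1/C2/C4 symmetry; estimates resolution by Fourier
    shell correlation at the 0.143 criterion; and measures tetramer geometry
    (diagonal distances, domain rotations, helix displacements) on atomic
    coordinate models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
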