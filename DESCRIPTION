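Package: menpi
Title: Forward Simulation of Magnetoelectric-Nanoparticle Magnetic Particle Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulator for mapping brain electric fields with
    magnetoelectric nanoparticles (MENs) imaged by magnetic particle imaging
    (MPI). Builds segmented head phantoms (WM/GM/CSF) with tissue
    conductivities, solves the quasi-static current-conduction problem for
    localized neuronal firing sources on a voxel grid, models superparamagnetic
    nanoparticle magnetization with Langevin statistics plus the linear
    magnetoelectric shift, forms field-free-point MPI images for conventional
    (MN) and magnetoelectric (MEN) particles, demodulates the MEN image by the
    MN image to recover the electric-field map, and performs dose, particle
    density, resolution and hysteresis-dissipation bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
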