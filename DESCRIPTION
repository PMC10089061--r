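Package: znmt
Title: Native Ion Mobility Mass Spectrometry and Gas-Phase Unfolding of
    Zinc Metallothionein-2 Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising partially metalated zinc
    metallothionein-2 (Zn4-7MT2) ions in the gas phase: exact-mass and fine
    isotope-pattern arithmetic for metal-bound, partially oxidised protein
    species with grid-search fitting of disulfide count and proton
    retention; travelling-wave ion mobility CCS calibration, collision
    induced unfolding (CIU) fingerprints and CIU50 estimation; kernel
    density conformer detection and multistage mobility gating; projection
    approximation collision cross sections from coordinates; and a
    desk-scale coarse-grained Langevin engine for thermal unfolding,
    steered dynamics on radius-of-gyration or end-to-end collective
    variables, and well-tempered metadynamics. A synthetic-data module
    generates sequences, zinc-thiolate cluster maps, dumbbell bead
    structures, spectra and fingerprints with controlled ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    igraph,
    bio3d,
    seqinr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
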