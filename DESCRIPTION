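Package: clcdyn
Title: Mechanistic Analyses for CLC Chloride/Proton Antiporter Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trajectory-, structure- and assay-level computations for
    dissecting the transport mechanism of CLC Cl-/H+ antiporters.
    Detects and classifies hydrogen-bonded water wires in molecular
    dynamics trajectories, calls chloride-unbinding and inner-gate
    opening events from smoothed distance series, computes cryo-EM map
    density z-scores at ion sites, performs Kabsch C-alpha RMSD
    comparisons between atomic models, normalizes hydrogen-deuterium
    exchange data across pH via an intrinsic-rate model, and quantifies
    per-transporter turnover rates and Cl-/H+ stoichiometry from
    proteoliposome flux assays. A seeded synthetic-data module generates
    fixtures with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
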