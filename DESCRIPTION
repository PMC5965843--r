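Package: ploopflex
Title: Conformational Comparison and Kinetics of P-Loop Phosphatases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing active and inactive conformers of
    protein tyrosine phosphatases of the dual-specificity (DUSP) fold,
    built around the temperature-switchable P-loop of the archaeal
    phosphatase Tk-PTP. Provides rigid-body (Kabsch) superposition with
    iterative outlier trimming, region RMSDs in a common frame, backbone
    dihedral tables with glycine-aware Ramachandran classification,
    peptide-bond flip detection, P-loop amide-orientation scoring
    (active/inactive state calls), hydrogen-bond network differencing,
    side-chain carbon-carbon packing-contact counting, and
    Michaelis-Menten kinetics fitting from fluorogenic progress curves.
    A synthetic-data module builds ideal-geometry polypeptides with
    prescribed dihedrals, rigid-motion and peptide-flip perturbations,
    multi-model dihedral ensembles, and simulated phosphatase assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
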