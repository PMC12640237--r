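Package: rnavae
Title: Ensemble RNA Secondary Structure Prediction with a Transformer
    Variational Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts RNA secondary structure as a conformational ensemble
    rather than a single optimum. A Transformer variational autoencoder with
    dynamic attention spans and learnable relative position bias maps a
    per-residue embedding (one-hot or a pretrained 640-dimensional language
    model representation) to base-pairing probability matrices; repeated
    sampling from the per-position latent space yields diverse structures.
    A greedy log-odds matching step discretizes probability matrices into
    base pairs under Watson-Crick/wobble and minimum-loop constraints,
    optionally allowing pseudoknots. Includes ensemble diversity summaries
    (positional entropy, pairwise structural diversity index), precision/
    recall/F1 evaluation, readers and writers for FASTA, dot-bracket, CT and
    BPSEQ, a synthetic stem-loop/pseudoknot generator with known ground
    truth, and windowed prediction with stitching for long sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
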