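Package: rnatopo
Title: Topological Classification and Prediction of Pseudoknotted RNA Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the topological genus of pseudoknotted RNA secondary
    structures via chord-diagram (fat-graph) boundary-component counting,
    together with its generalizations, the genus trace and the fingerprint
    matrix. Reproduces the genus-resolved diagram expansion of toy
    matrix-model partition functions by exact combinatorial enumeration,
    and predicts pseudoknotted structures from sequence with a Metropolis
    Monte-Carlo folding engine over helipoints carrying a topological
    chemical potential penalizing genus. Includes readers and writers for
    extended dot-bracket, BPSEQ and CT formats, ensemble genus-trace
    summaries with Gaussian smoothing, genus-versus-length regression, and
    a synthetic fixture generator for pseudoknot topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
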