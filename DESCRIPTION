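Package: drugcombnet
Title: Network and Chemistry Based Druggability Evaluation and Drug
    Combination Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for evaluating the druggability of a disease from
    transcriptomics and drug-library data. Selects disease-relevant genes
    with a rank-sum location test and a variance-ratio stability test,
    infers a consensus co-expression network from an ensemble of
    correlation and mutual-information methods, quantifies drug-drug
    relationships by the Hamming-Ipsen-Mikhailov distance between
    perturbational networks, by chemical structure (circular fingerprints
    with Tanimoto similarity, maximal common substructure, Levenshtein
    distance on canonical SMILES), and by target topology on the disease
    network (area of action, shortest-path target distances), and derives
    Pareto-optimal drug combinations with a five-objective NSGA-II
    genetic algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools,
    MASS,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
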