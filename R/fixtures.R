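# Synthetic inputs with known ground truth: expression data with planted
# co-expression blocks, shifted genes and variance genes, plus a toy drug
# library with real small-molecule SMILES and rewired perturbational
# networks. Used throughout the test suite; also exposed on the CLI.

#' Specification of a synthetic expression dataset
#'
#' @param n_genes total genes.
#' @param n_samples_per_condition samples in each of disease and control.
#' @param n_blocks number of planted co-expression blocks.
#' @param block_size genes per block.
#' @param rho within-block correlation in (0, 1).
#' @param n_shifted genes whose disease mean is shifted by `delta`.
#' @param delta shift in units of the within-gene standard deviation.
#' @param n_variance genes whose disease variance is scaled by `kappa`.
#' @param kappa variance ratio for the variance genes.
#' @param seed RNG seed.
#' @return validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 100, n_samples_per_condition = 10,
                           n_blocks = 3, block_size = 10, rho = 0.9,
                           n_shifted = 10, delta = 3,
                           n_variance = 10, kappa = 4, seed = 1) {
  stopifnot(n_genes >= 3, n_samples_per_condition >= 2,
            n_blocks >= 0, block_size >= 2, rho > 0, rho < 1,
            n_shifted >= 0, n_variance >= 0, kappa > 0)
  if (n_blocks * block_size + n_shifted + n_variance > n_genes)
    stop("planted structures exceed n_genes; they must be disjoint")
  structure(list(n_genes = n_genes,
                 n_samples_per_condition = n_samples_per_condition,
                 n_blocks = n_blocks, block_size = block_size, rho = rho,
                 n_shifted = n_shifted, delta = delta,
                 n_variance = n_variance, kappa = kappa, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Control samples: genes i.i.d. standard normal except the planted
#' blocks, which are drawn from a multivariate normal with off-diagonal
#' correlation `rho`. Disease samples: same generative process, plus
#' `delta` added to the shifted genes and standard deviation scaled by
#' `sqrt(kappa)` on the variance genes. Planted gene groups are disjoint:
#' blocks first, then shifted genes, then variance genes.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (block membership, block edge table, shifted and variance gene ids).
#' @export
make_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes; n <- spec$n_samples_per_condition
  genes <- sprintf("G%04d", seq_len(ng))
  blocks <- if (spec$n_blocks > 0)
    lapply(seq_len(spec$n_blocks), function(b)
      genes[((b - 1) * spec$block_size + 1):(b * spec$block_size)])
  else list()
  off <- spec$n_blocks * spec$block_size
  shifted <- if (spec$n_shifted > 0) genes[off + seq_len(spec$n_shifted)]
             else character(0)
  off <- off + spec$n_shifted
  var_genes <- if (spec$n_variance > 0) genes[off + seq_len(spec$n_variance)]
               else character(0)

  draw_condition <- function(n_s) {
    m <- matrix(stats::rnorm(ng * n_s), nrow = ng,
                dimnames = list(genes, NULL))
    for (bl in blocks) {
      S <- matrix(spec$rho, length(bl), length(bl))
      diag(S) <- 1
      m[bl, ] <- t(MASS::mvrnorm(n_s, mu = rep(0, length(bl)), Sigma = S))
    }
    m
  }
  ctrl <- draw_condition(n)
  dis <- draw_condition(n)
  if (length(shifted) > 0)
    dis[shifted, ] <- dis[shifted, ] + spec$delta
  if (length(var_genes) > 0)
    dis[var_genes, ] <- dis[var_genes, ] * sqrt(spec$kappa)

  vals <- cbind(dis, ctrl)
  colnames(vals) <- c(sprintf("D%03d", seq_len(n)), sprintf("C%03d", seq_len(n)))
  cond <- setNames(rep(c("disease", "control"), each = n), colnames(vals))

  block_edges <- if (length(blocks) > 0)
    do.call(rbind, lapply(blocks, function(bl) {
      p <- combn(sort(bl), 2)
      data.frame(from = p[1, ], to = p[2, ], stringsAsFactors = FALSE)
    }))
  else data.frame(from = character(0), to = character(0))

  list(dataset = expression_dataset(vals, cond),
       truth = list(blocks = blocks, block_edges = block_edges,
                    shifted_genes = shifted, variance_genes = var_genes))
}

# Real small-molecule SMILES used by the toy library.
fixture_smiles <- function() {
  c(aspirin = "CC(=O)OC1=CC=CC=C1C(=O)O",
    caffeine = "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
    ibuprofen = "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",
    paracetamol = "CC(=O)NC1=CC=C(O)C=C1",
    metformin = "CN(C)C(=N)NC(=N)N",
    ethanol = "CCO",
    benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1",
    naproxen = "COC1=CC2=CC=C(C=C2C=C1)C(C)C(=O)O",
    nicotine = "CN1CCCC1c1cccnc1",
    salicylic_acid = "OC(=O)c1ccccc1O",
    benzoic_acid = "OC(=O)c1ccccc1",
    acetone = "CC(=O)C",
    glycerol = "OCC(O)CO",
    urea = "NC(=O)N",
    pyridine = "c1ccncc1",
    aniline = "Nc1ccccc1",
    cyclohexane = "C1CCCCC1",
    hexane = "CCCCCC",
    acetic_acid = "CC(=O)O",
    propanol = "CCCO",
    isopropanol = "CC(C)O",
    diethyl_ether = "CCOCC")
}

#' Rewire a fraction of a network's edges
#'
#' Removes `k` randomly chosen edges and adds `k` randomly chosen
#' non-edges over the same node set, preserving node identity and edge
#' count. More rewires give a larger expected distance to the original
#' network, which is what the drug-library fixture relies on.
#'
#' @param net igraph network.
#' @param k number of edges to rewire.
#' @return rewired igraph network.
#' @export
rewire_network <- function(net, k) {
  ed <- network_edges(net)
  nodes <- igraph::V(net)$name
  if (k == 0) return(gene_network(ed, nodes = nodes))
  k <- min(k, nrow(ed))
  all_pairs <- edge_universe(nodes)
  key <- function(df) paste(df$from, df$to, sep = "|")
  non_edges <- all_pairs[!(key(all_pairs) %in% key(ed)), , drop = FALSE]
  k <- min(k, nrow(non_edges))
  drop_idx <- sample(nrow(ed), k)
  add_idx <- sample(nrow(non_edges), k)
  added <- non_edges[add_idx, , drop = FALSE]
  added$weight <- ed$weight[drop_idx]
  kept <- ed[-drop_idx, , drop = FALSE]
  gene_network(rbind(kept, added), nodes = nodes)
}

#' Generate a toy drug library with known structure
#'
#' Drugs carry real small-molecule SMILES (hard-coded list), targets
#' assigned deterministically over the supplied disease network's nodes
#' (round-robin, 2 targets each), and perturbational networks built as
#' seeded edge rewires of the disease network: drug `i` rewires
#' `rewires[i]` edges, so the expected mechanism-of-action distance to the
#' disease network grows along the library.
#'
#' @param n_drugs number of drugs (2..24).
#' @param network igraph disease network the perturbational networks are
#'   derived from.
#' @param rewires integer vector of per-drug rewire counts (recycled);
#'   default spreads 0..half the edge count over the library.
#' @param seed RNG seed.
#' @return a `drug_library`.
#' @export
make_drug_library <- function(n_drugs, network, rewires = NULL, seed = 1) {
  if (n_drugs < 2 || n_drugs > 24)
    stop("n_drugs must be between 2 and 24")
  smiles <- fixture_smiles()[seq_len(n_drugs)]
  nodes <- sort(igraph::V(network)$name)
  if (length(nodes) < 2) stop("network too small for target assignment")
  ne <- igraph::ecount(network)
  if (is.null(rewires))
    rewires <- round(seq(0, max(1, ne %/% 2), length.out = n_drugs))
  rewires <- rep_len(rewires, n_drugs)
  set.seed(seed)
  recs <- lapply(seq_len(n_drugs), function(i) {
    tgt <- nodes[(c(2 * i - 2, 2 * i - 1) %% length(nodes)) + 1]
    drug_record(names(smiles)[i], smiles = unname(smiles[i]),
                targets = unique(tgt),
                network = rewire_network(network, rewires[i]))
  })
  names(recs) <- names(smiles)
  structure(recs, class = "drug_library")
}
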