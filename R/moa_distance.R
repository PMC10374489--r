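# Hamming-Ipsen-Mikhailov (HIM) distance between gene networks.
#
# The Hamming term is the normalized edge-weight L1 difference; the
# Ipsen-Mikhailov term is the L2 distance between Lorentzian-broadened
# spectral densities of the two graph Laplacians, with the Lorentzian
# width gamma calibrated per node count so that the empty/complete pair is
# at distance exactly 1. HIM = sqrt(H^2 + xi*IM^2) / sqrt(1 + xi).

#' Align two networks over their node-set union
#'
#' @param g1,g2 igraph gene networks (possibly over different gene sets).
#' @return list of class `aligned_graph_pair` with the canonically ordered
#'   common node vector `nodes` and weighted adjacency matrices `A`, `B`
#'   (nodes absent from one graph are isolated in it).
#' @export
align_graphs <- function(g1, g2) {
  n1 <- if (igraph::vcount(g1) > 0) igraph::V(g1)$name else character(0)
  n2 <- if (igraph::vcount(g2) > 0) igraph::V(g2)$name else character(0)
  nodes <- sort(unique(c(n1, n2)))
  if (length(nodes) == 0) stop("both graphs are empty")
  adj <- function(g, present) {
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    ed <- network_edges(g)
    if (nrow(ed) > 0) {
      A[cbind(ed$from, ed$to)] <- ed$weight
      A[cbind(ed$to, ed$from)] <- ed$weight
    }
    A
  }
  structure(list(nodes = nodes, A = adj(g1), B = adj(g2),
                 n = length(nodes)),
            class = "aligned_graph_pair")
}

#' Normalized Hamming distance between aligned graphs
#'
#' `H = sum_{i<j} |a_ij - b_ij| / choose(N, 2)`, in \[0, 1\] for weights in
#' \[0, 1\].
#'
#' @param p an [align_graphs()] pair.
#' @return numeric scalar in \[0, 1\].
#' @export
hamming_distance <- function(p) {
  stopifnot(inherits(p, "aligned_graph_pair"))
  if (p$n < 2) stop("need >= 2 nodes")
  d <- abs(p$A - p$B)
  sum(d[upper.tri(d)]) / choose(p$n, 2)
}

# Laplacian vibrational frequencies omega_i = sqrt(lambda_i), i = 2..N.
laplacian_frequencies <- function(A) {
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[1] < -1e-6) stop("Laplacian eigenvalue substantially negative")
  ev <- pmax(ev, 0)
  sqrt(ev[-1])
}

# Lorentzian spectral density on [0, Inf), normalized in closed form:
# each Lorentzian centred at w_i integrates to pi/2 + atan(w_i/gamma).
spectral_density <- function(omega_centres, gamma) {
  K <- 1 / sum(pi / 2 + atan(omega_centres / gamma))
  function(w)
    K * vapply(w, function(wi)
      sum(gamma / ((wi - omega_centres)^2 + gamma^2)), numeric(1))
}

#' Ipsen-Mikhailov spectral distance
#'
#' L2 distance between the Lorentzian-broadened Laplacian spectral
#' densities of the two graphs, integrated by adaptive quadrature on
#' `[0, omega_max + 20*gamma]` with absolute tolerance 1e-8.
#'
#' @param p an [align_graphs()] pair.
#' @param gamma Lorentzian half-width at half-maximum; defaults to
#'   [find_gamma()] of the pair's node count, which normalizes the
#'   empty-vs-complete distance to 1.
#' @return numeric scalar in \[0, 1\] (up to quadrature tolerance).
#' @export
ipsen_mikhailov <- function(p, gamma = NULL) {
  stopifnot(inherits(p, "aligned_graph_pair"))
  if (p$n < 2) stop("need >= 2 nodes")
  if (is.null(gamma)) gamma <- find_gamma(p$n)
  if (gamma <= 0) stop("gamma must be > 0")
  wA <- laplacian_frequencies(p$A)
  wB <- laplacian_frequencies(p$B)
  im_from_frequencies(wA, wB, gamma)
}

im_from_frequencies <- function(wA, wB, gamma) {
  rhoA <- spectral_density(wA, gamma)
  rhoB <- spectral_density(wB, gamma)
  upper <- max(wA, wB, 0) + 20 * gamma
  val <- stats::integrate(function(w) (rhoA(w) - rhoB(w))^2, 0, upper,
                          abs.tol = 1e-8, rel.tol = 1e-8,
                          subdivisions = 1000L)$value
  sqrt(max(0, val))
}

.gamma_cache <- new.env(parent = emptyenv())

#' Calibrate the Lorentzian width for a node count
#'
#' Finds the unique `gamma > 0` at which the Ipsen-Mikhailov distance
#' between the empty and the complete unweighted graph on `n` nodes equals
#' 1, by bisection on \[1e-4, 10\] to 1e-10. Cached per `n`.
#'
#' @param n node count (>= 2).
#' @return calibrated gamma.
#' @export
find_gamma <- function(n) {
  if (n < 2) stop("n must be >= 2")
  key <- as.character(n)
  if (!is.null(.gamma_cache[[key]])) return(.gamma_cache[[key]])
  w_empty <- rep(0, n - 1)
  w_complete <- rep(sqrt(n), n - 1)
  f <- function(g) im_from_frequencies(w_empty, w_complete, g) - 1
  lo <- 1e-4; hi <- 10
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) stop("bisection bracket does not contain the root")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  g <- (lo + hi) / 2
  .gamma_cache[[key]] <- g
  g
}

#' Hamming-Ipsen-Mikhailov distance
#'
#' `HIM = sqrt(H^2 + xi * IM^2) / sqrt(1 + xi)`. `xi = 1` mixes the local
#' (Hamming) and global (spectral) terms equally; `xi -> 0` recovers H and
#' `xi -> Inf` recovers IM.
#'
#' @param p an [align_graphs()] pair.
#' @param xi non-negative mixing weight (default 1).
#' @param gamma optional Lorentzian width override.
#' @return numeric scalar in \[0, 1\].
#' @export
him <- function(p, xi = 1, gamma = NULL) {
  if (xi < 0) stop("xi must be >= 0")
  H <- hamming_distance(p)
  IM <- ipsen_mikhailov(p, gamma = gamma)
  sqrt(H^2 + xi * IM^2) / sqrt(1 + xi)
}

#' Pairwise mechanism-of-action distance matrix
#'
#' HIM distance between the perturbational networks of every drug pair.
#' Each pair is aligned over its own node-set union, so gamma is
#' recalibrated (and cached) per pair size.
#'
#' @param drugs a `drug_library`; every record needs a perturbational
#'   network.
#' @param xi HIM mixing weight.
#' @param binarize if `TRUE`, weights are thresholded at > 0 before the
#'   distance is computed.
#' @return symmetric distance matrix labeled by drug id.
#' @export
moa_matrix <- function(drugs, xi = 1, binarize = FALSE) {
  missing_net <- names(drugs)[vapply(drugs, function(d) is.null(d$network),
                                     logical(1))]
  if (length(missing_net) > 0)
    stop("drugs without perturbational network: ",
         paste(missing_net, collapse = ", "))
  ids <- names(drugs)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      p <- align_graphs(drugs[[ids[i]]]$network, drugs[[ids[j]]]$network)
      if (binarize) {
        p$A <- (p$A > 0) * 1
        p$B <- (p$B > 0) * 1
      }
      m[i, j] <- m[j, i] <- him(p, xi = xi)
    }
  }
  m
}
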