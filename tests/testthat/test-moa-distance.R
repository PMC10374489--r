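test_that("graph alignment embeds both graphs over the node union", {
  g1 <- gene_network(data.frame(from = "A", to = "B"))
  g2 <- gene_network(data.frame(from = "B", to = "C"))
  p <- align_graphs(g1, g2)
  expect_equal(p$nodes, c("A", "B", "C"))
  expect_equal(p$A["C", ], c(A = 0, B = 0, C = 0))
  expect_equal(p$B["A", ], c(A = 0, B = 0, C = 0))

  pid <- align_graphs(g1, g1)
  expect_equal(pid$A, pid$B)

  g3 <- gene_network(data.frame(from = "X", to = "Y"))
  pd <- align_graphs(g1, g3)
  expect_equal(pd$n, 4)
  expect_equal(sum(pd$A[c("X", "Y"), ]), 0)
  expect_equal(sum(pd$B[c("A", "B"), ]), 0)

  e0 <- gene_network(NULL)
  expect_error(align_graphs(e0, e0), "empty")
})

test_that("Hamming distance counts normalized edge differences", {
  nodes <- LETTERS[1:4]
  empty <- gene_network(NULL, nodes = nodes)
  complete <- gene_network(edge_universe(nodes))
  expect_equal(hamming_distance(align_graphs(empty, complete)), 1)
  expect_equal(hamming_distance(align_graphs(complete, complete)), 0)

  g1 <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C")),
                     nodes = nodes)
  g2 <- gene_network(data.frame(from = c("A", "C"), to = c("B", "D")),
                     nodes = nodes)
  # differ in exactly B-C and C-D: 2 of 6 pairs
  expect_equal(hamming_distance(align_graphs(g1, g2)), 2 / 6)
})

test_that("gamma calibration puts the empty/complete pair at IM = 1", {
  for (n in c(5, 10)) {
    g <- find_gamma(n)
    empty <- gene_network(NULL, nodes = sprintf("N%02d", 1:n))
    complete <- gene_network(edge_universe(sprintf("N%02d", 1:n)))
    p <- align_graphs(empty, complete)
    expect_lt(abs(ipsen_mikhailov(p, g) - 1), 1e-6)
    expect_identical(find_gamma(n), g)  # cached and deterministic
  }
  expect_error(find_gamma(1), ">= 2")
})

test_that("bisection gamma agrees with a dense grid scan", {
  n <- 4
  g_bis <- find_gamma(n)
  w_e <- rep(0, n - 1); w_c <- rep(sqrt(n), n - 1)
  grid <- seq(0.05, 2, length.out = 2000)
  vals <- vapply(grid, function(g) {
    up <- sqrt(n) + 20 * g
    w <- seq(0, up, length.out = 20000)
    dens <- function(wc) {
      K <- 1 / sum(pi / 2 + atan(wc / g))
      K * rowSums(g / (outer(w, wc, "-")^2 + g^2))
    }
    f <- (dens(w_e) - dens(w_c))^2
    abs(sqrt(sum((f[-1] + f[-length(w)]) / 2) * (w[2] - w[1])) - 1)
  }, numeric(1))
  g_grid <- grid[which.min(vals)]
  expect_lt(abs(g_bis - g_grid), diff(grid[1:2]) * 2)
})

test_that("adaptive-quadrature IM matches a dense trapezoid oracle", {
  set.seed(7)
  for (rep in 1:6) {
    n <- sample(4:12, 1)
    g1 <- random_gene_network(n)
    g2 <- random_gene_network(n)
    p <- align_graphs(g1, g2)
    gam <- find_gamma(p$n)
    expect_lt(abs(ipsen_mikhailov(p, gam) -
                    oracle_im_trapezoid(p, gam, npts = 2e5)), 1e-5)
  }
  # the spec's fixed pair: 5-node path vs 5-node star
  path5 <- gene_network(data.frame(from = sprintf("N%d", 1:4),
                                   to = sprintf("N%d", 2:5)))
  star5 <- gene_network(data.frame(from = "N1", to = sprintf("N%d", 2:5)))
  p <- align_graphs(path5, star5)
  gam <- find_gamma(5)
  expect_lt(abs(ipsen_mikhailov(p, gam) -
                  oracle_im_trapezoid(p, gam, npts = 1e6)), 1e-6)
})

test_that("HIM composes its two terms and respects the xi limits", {
  nodes <- LETTERS[1:4]
  g1 <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C")),
                     nodes = nodes)
  g2 <- gene_network(data.frame(from = c("A", "C"), to = c("B", "D")),
                     nodes = nodes)
  p <- align_graphs(g1, g2)
  H <- hamming_distance(p)
  IM <- ipsen_mikhailov(p)
  expect_equal(him(p, xi = 1), sqrt(H^2 + IM^2) / sqrt(2), tolerance = 1e-10)
  expect_equal(him(p, xi = 1e-8), H, tolerance = 1e-4)
  expect_equal(him(p, xi = 1e8), IM, tolerance = 1e-4)
  expect_equal(him(align_graphs(g1, g1)), 0)

  empty <- gene_network(NULL, nodes = nodes)
  complete <- gene_network(edge_universe(nodes))
  expect_equal(him(align_graphs(empty, complete)), 1, tolerance = 1e-5)
  expect_error(him(p, xi = -1), "xi")
})

test_that("IM is invariant under consistent node relabeling", {
  set.seed(13)
  g <- random_gene_network(8)
  ed <- network_edges(g)
  relabel <- setNames(sprintf("Z%02d", sample(8)), sort(igraph::V(g)$name))
  ed2 <- data.frame(from = relabel[ed$from], to = relabel[ed$to],
                    weight = ed$weight)
  g2 <- gene_network(ed2, nodes = unname(relabel))
  p1 <- align_graphs(g, g)
  gam <- find_gamma(8)
  # compare spectra via IM against a common reference (the empty graph)
  empty1 <- gene_network(NULL, nodes = igraph::V(g)$name)
  empty2 <- gene_network(NULL, nodes = unname(relabel))
  im1 <- ipsen_mikhailov(align_graphs(g, empty1), gam)
  im2 <- ipsen_mikhailov(align_graphs(g2, empty2), gam)
  expect_equal(im1, im2, tolerance = 1e-10)
})

test_that("H, IM and HIM behave as bounded symmetric distances on random triples", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    gs <- lapply(1:3, function(i) random_gene_network(n))
    gam <- find_gamma(n)
    d <- function(i, j, fun) fun(align_graphs(gs[[i]], gs[[j]]))
    for (fun in list(hamming_distance,
                     function(p) ipsen_mikhailov(p, gam),
                     function(p) him(p, gamma = gam))) {
      d12 <- d(1, 2, fun); d13 <- d(1, 3, fun); d23 <- d(2, 3, fun)
      expect_true(all(c(d12, d13, d23) >= 0))
      expect_true(all(c(d12, d13, d23) <= 1 + 1e-9))
      expect_equal(d12, fun(align_graphs(gs[[2]], gs[[1]])), tolerance = 1e-9)
      expect_lte(d12, d13 + d23 + 1e-9)
    }
  }
})

test_that("the MOA matrix is symmetric and element-wise equal to him()", {
  sp <- synthetic_spec(n_genes = 20, n_samples_per_condition = 5,
                       n_blocks = 2, block_size = 5, n_shifted = 0,
                       n_variance = 0, seed = 2)
  fx <- make_expression(sp)
  base <- gene_network(fx$truth$block_edges)
  lib <- make_drug_library(4, base, rewires = c(0, 3, 6, 9), seed = 3)
  m <- moa_matrix(lib)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_true(all(m >= 0 & m <= 1))
  p <- align_graphs(lib[[2]]$network, lib[[4]]$network)
  expect_equal(m[2, 4], him(p), tolerance = 1e-12)

  # identical networks sit at distance zero
  lib2 <- lib
  lib2[[2]]$network <- lib2[[1]]$network
  m2 <- moa_matrix(lib2)
  expect_equal(m2[1, 2], 0)

  lib3 <- lib
  lib3[[3]]$network <- NULL
  expect_error(moa_matrix(lib3), "without perturbational network")
})
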