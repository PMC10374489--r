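# Independent brute-force oracles used across the suite. None of these
# call the package's own implementation paths.

# Exact two-sided rank-sum p-value by full permutation enumeration.
oracle_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  stat <- function(idx) sum(rank(all_v)[idx]) - n1 * (n1 + 1) / 2  # U of group 1
  obs <- stat(seq_len(n1))
  combos <- combn(length(all_v), n1)
  us <- apply(combos, 2, stat)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Two-sided F-test p-value by numeric integration of the F density.
oracle_f_p <- function(f, d1, d2) {
  dens <- function(t) stats::df(t, d1, d2)
  lower <- stats::integrate(dens, 0, f, rel.tol = 1e-10)$value
  min(1, 2 * min(lower, 1 - lower))
}

# BH step-up adjusted p-values, computed from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in rev(seq_len(n))) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  pmin(1, q)
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix
# (unweighted hops).
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Non-dominated set by explicit O(n^2) pairwise checking (minimize all).
oracle_pareto <- function(objs) {
  n <- nrow(objs)
  nd <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(objs[j, ] <= objs[i, ]) && any(objs[j, ] < objs[i, ])) {
        dominated <- TRUE
        break
      }
    }
    nd[i] <- !dominated
  }
  nd
}

# Ipsen-Mikhailov distance by dense trapezoid integration.
oracle_im_trapezoid <- function(p, gamma, npts = 1e6) {
  freqs <- function(A) {
    L <- diag(rowSums(A)) - A
    ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    sqrt(pmax(ev, 0))[-1]
  }
  wA <- freqs(p$A); wB <- freqs(p$B)
  dens <- function(w, wc) {
    K <- 1 / sum(pi / 2 + atan(wc / gamma))
    K * rowSums(gamma / (outer(w, wc, "-")^2 + gamma^2))
  }
  up <- max(wA, wB, 0) + 20 * gamma
  w <- seq(0, up, length.out = npts)
  f <- (dens(w, wA) - dens(w, wB))^2
  sqrt(sum((f[-1] + f[-npts]) / 2) * (w[2] - w[1]))
}

# Levenshtein distance from the recursive definition (memoized).
oracle_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- matrix(NA_integer_, length(a) + 1, length(b) + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0) j else if (j == 0) i else
      min(rec(i - 1, j) + 1, rec(i, j - 1) + 1,
          rec(i - 1, j - 1) + (a[i] != b[j]))
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(length(a), length(b))
}

# Maximum common connected subgraph size on tiny labeled graphs by
# exhaustive mapping enumeration (atoms: label vectors; bonds: label
# matrices with NA for no bond).
oracle_mcs_atoms <- function(lab1, b1, lab2, b2) {
  n1 <- length(lab1); n2 <- length(lab2)
  best <- 0L
  rec <- function(m1, m2) {
    if (length(m1) > best) best <<- length(m1)
    for (a in setdiff(seq_len(n1), m1)) {
      for (b in setdiff(seq_len(n2), m2)) {
        if (lab1[a] != lab2[b]) next
        if (length(m1) > 0) {
          linked <- FALSE
          for (k in seq_along(m1)) {
            l1 <- b1[a, m1[k]]; l2 <- b2[b, m2[k]]
            if (!is.na(l1) && !is.na(l2) && l1 == l2) { linked <- TRUE; break }
          }
          if (!linked) next
        }
        rec(c(m1, a), c(m2, b))
      }
    }
  }
  rec(integer(0), integer(0))
  best
}

# Shared tiny fixtures -------------------------------------------------------

make_star5 <- function() {
  gene_network(data.frame(from = "HUB", to = paste0("L", 1:4)))
}

make_path4 <- function() {
  gene_network(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")))
}

random_gene_network <- function(n, p = 0.4, weighted = TRUE) {
  nodes <- sprintf("N%02d", seq_len(n))
  uni <- edge_universe(nodes)
  keep <- stats::runif(nrow(uni)) < p
  uni$weight <- if (weighted) stats::runif(nrow(uni)) else 1
  gene_network(uni[keep, , drop = FALSE], nodes = nodes)
}

tiny_expression <- function(n_genes = 6, n_per = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * 2 * n_per), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(2 * n_per))))
  cond <- stats::setNames(rep(c("disease", "control"), each = n_per),
                          colnames(m))
  expression_dataset(m, cond)
}
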