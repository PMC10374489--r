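# Consensus co-expression network inference: rank edges with an ensemble of
# correlation and mutual-information methods, aggregate the rankings by mean
# rank (Borda), and cut the consensus to a network.

#' Canonical unordered gene-pair universe
#' @param genes character vector of gene symbols.
#' @return data.frame `from`, `to` with `from < to`, lexicographic order.
#' @export
edge_universe <- function(genes) {
  genes <- sort(unique(as.character(genes)))
  if (length(genes) < 2) stop("need >= 2 genes")
  idx <- combn(genes, 2)
  data.frame(from = idx[1, ], to = idx[2, ], stringsAsFactors = FALSE)
}

# Equal-width discretization with ceiling(sqrt(n)) bins per gene.
discretize_rows <- function(m) {
  nb <- ceiling(sqrt(ncol(m)))
  t(apply(m, 1, function(x) {
    r <- range(x)
    if (diff(r) == 0) return(rep(1L, length(x)))
    b <- pmin(nb, 1L + floor((x - r[1]) / diff(r) * nb))
    as.integer(b)
  }))
}

# Mutual information (nats) between all row pairs of a discretized matrix.
mi_matrix <- function(d) {
  p <- nrow(d); n <- ncol(d)
  mi <- matrix(0, p, p, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tab <- table(d[i, ], d[j, ]) / n
      px <- rowSums(tab); py <- colSums(tab)
      nz <- tab > 0
      v <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
      mi[i, j] <- mi[j, i] <- max(0, v)
    }
  }
  mi
}

clr_scores <- function(mi) {
  p <- nrow(mi)
  mu <- numeric(p); sg <- numeric(p)
  for (i in seq_len(p)) {
    row <- mi[i, -i]
    mu[i] <- mean(row)
    sg[i] <- stats::sd(row)
  }
  z <- matrix(0, p, p)
  for (i in seq_len(p)) {
    zi <- if (sg[i] > 0) pmax(0, (mi[i, ] - mu[i]) / sg[i]) else rep(0, p)
    z[i, ] <- zi
  }
  s <- sqrt(z^2 + t(z)^2)
  dimnames(s) <- dimnames(mi)
  s
}

# Data-processing-inequality pruning: within every triangle drop the weakest
# edge when it is strictly below the minimum of the other two (tolerance 0).
# For the edge *ranking*, pruned edges are ordered below every retained edge
# but keep their relative MI order (offsetting retained scores by max(MI)+1),
# instead of collapsing into one large tie at zero.
aracne_scores <- function(mi, tol = 0) {
  p <- nrow(mi)
  keep <- matrix(TRUE, p, p)
  for (i in seq_len(p - 2)) {
    for (j in (i + 1):(p - 1)) {
      for (k in (j + 1):p) {
        e <- c(mi[i, j], mi[i, k], mi[j, k])
        w <- which.min(e)
        if (e[w] < min(e[-w]) - tol) {
          if (w == 1) keep[i, j] <- keep[j, i] <- FALSE
          if (w == 2) keep[i, k] <- keep[k, i] <- FALSE
          if (w == 3) keep[j, k] <- keep[k, j] <- FALSE
        }
      }
    }
  }
  s <- mi + keep * (max(mi) + 1)
  diag(s) <- 0
  dimnames(s) <- dimnames(mi)
  s
}

# Max-relevance min-redundancy forward selection per target; edge score is
# the larger of the two directed selection criteria. Edges never selected in
# either direction are ordered below all selected edges, by raw MI.
mrnet_scores <- function(mi) {
  p <- nrow(mi)
  s <- matrix(0, p, p, dimnames = dimnames(mi))
  for (tgt in seq_len(p)) {
    rest <- setdiff(seq_len(p), tgt)
    selected <- integer(0)
    avail <- rest
    while (length(avail) > 0) {
      crit <- vapply(avail, function(x) {
        red <- if (length(selected) == 0) 0 else mean(mi[x, selected])
        mi[x, tgt] - red
      }, numeric(1))
      best <- which.max(crit)
      if (crit[best] <= 0) break
      x <- avail[best]
      s[x, tgt] <- max(s[x, tgt], crit[best])
      selected <- c(selected, x)
      avail <- avail[-best]
    }
  }
  s <- pmax(s, t(s))
  off <- max(mi) + 1
  sel <- s > 0
  s[sel] <- s[sel] + off
  s[!sel] <- mi[!sel]
  diag(s) <- 0
  s
}

#' Rank all gene pairs with a single inference method
#'
#' Correlation methods rank by absolute Pearson or Spearman correlation.
#' Mutual-information methods discretize each gene into
#' `ceiling(sqrt(n))` equal-width bins, estimate pairwise MI, and score
#' edges by the CLR background z-score, ARACNE DPI-pruned MI, or MRNET
#' max-relevance-min-redundancy criteria.
#'
#' @param ds an [expression_dataset()] (typically restricted to selected
#'   genes and, for a disease network, to disease samples).
#' @param method one of `"pearson"`, `"spearman"`, `"clr"`, `"aracne"`,
#'   `"mrnet"`.
#' @param condition which samples to use: `"disease"` (default), `"control"`
#'   or `"all"`.
#' @return An edge ranking: data.frame `from`, `to`, `score`, `rank`
#'   (rank 1 = strongest, average ranks on ties), with attribute `method`.
#' @export
infer_single <- function(ds, method = c("pearson", "spearman", "clr",
                                        "aracne", "mrnet"),
                         condition = c("disease", "control", "all")) {
  method <- match.arg(method)
  condition <- match.arg(condition)
  m <- ds$values
  if (condition != "all") m <- m[, ds$condition == condition, drop = FALSE]
  if (ncol(m) < 3) stop("need >= 3 samples")
  if (nrow(m) < 3) stop("need >= 3 genes")
  m <- m[order(rownames(m)), , drop = FALSE]

  score_mat <- switch(method,
    pearson = abs(stats::cor(t(m), method = "pearson")),
    spearman = abs(stats::cor(t(m), method = "spearman")),
    clr = clr_scores(mi_matrix(discretize_rows(m))),
    aracne = aracne_scores(mi_matrix(discretize_rows(m))),
    mrnet = mrnet_scores(mi_matrix(discretize_rows(m))))
  score_mat[is.na(score_mat)] <- 0

  uni <- edge_universe(rownames(m))
  sc <- score_mat[cbind(uni$from, uni$to)]
  out <- data.frame(from = uni$from, to = uni$to, score = sc,
                    rank = rank(-sc, ties.method = "average"),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

#' Aggregate edge rankings into a consensus (Borda mean rank)
#'
#' The consensus score of an edge is the mean of its per-method ranks;
#' edges are re-ranked by ascending mean rank with lexicographic edge-label
#' tie-breaking, so the result is deterministic and invariant to the order
#' of the input rankings.
#'
#' @param rankings list of edge rankings from [infer_single()], all over
#'   the same gene-pair universe.
#' @return consensus edge ranking (`from`, `to`, `mean_rank`, `rank`).
#' @export
aggregate_rankings <- function(rankings) {
  if (length(rankings) < 2) stop("need >= 2 rankings")
  key <- function(r) paste(r$from, r$to, sep = "|")
  base <- rankings[[1]][order(key(rankings[[1]])), c("from", "to")]
  k0 <- paste(base$from, base$to, sep = "|")
  rank_mat <- vapply(rankings, function(r) {
    k <- key(r)
    missing <- setdiff(k0, k)
    extra <- setdiff(k, k0)
    if (length(missing) > 0 || length(extra) > 0)
      stop("edge universes differ; missing pairs: ",
           paste(head(c(missing, extra), 10), collapse = ", "))
    r$rank[match(k0, k)]
  }, numeric(nrow(base)))
  mean_rank <- rowMeans(rank_mat)
  ord <- order(mean_rank, base$from, base$to)
  out <- base[ord, , drop = FALSE]
  out$mean_rank <- mean_rank[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "method") <- "consensus"
  out
}

#' Cut a consensus ranking to a network
#'
#' @param consensus an edge ranking (consensus or single-method).
#' @param top_k keep this many strongest edges; exactly one of `top_k` /
#'   `top_frac` must be given.
#' @param top_frac keep this fraction of all edges (default cut in the
#'   pipeline is 0.05).
#' @return igraph network of the kept edges; isolated genes are dropped and
#'   edge weight is `1 - (rank - 1) / E` in (0, 1].
#' @export
threshold_network <- function(consensus, top_k = NULL, top_frac = NULL) {
  if (is.null(top_k) == is.null(top_frac))
    stop("give exactly one of top_k / top_frac")
  E <- nrow(consensus)
  k <- if (!is.null(top_k)) top_k else max(1L, round(top_frac * E))
  if (k > E) {
    warning(sprintf("top_k = %d exceeds %d available edges; keeping all", k, E))
    k <- E
  }
  ord <- order(consensus$rank, consensus$from, consensus$to)
  kept <- consensus[ord, ][seq_len(k), , drop = FALSE]
  kept$weight <- 1 - (kept$rank - 1) / E
  gene_network(kept[, c("from", "to", "weight")])
}

#' Ensemble consensus network in one call
#'
#' @param ds an [expression_dataset()].
#' @param methods character vector of method names for [infer_single()].
#' @param top_k,top_frac cut rule passed to [threshold_network()].
#' @param condition sample subset, see [infer_single()].
#' @return igraph consensus network.
#' @export
infer_consensus_network <- function(ds,
                                    methods = c("pearson", "spearman", "clr",
                                                "aracne", "mrnet"),
                                    top_k = NULL, top_frac = 0.05,
                                    condition = "disease") {
  rankings <- lapply(methods, function(mth)
    infer_single(ds, method = mth, condition = condition))
  cons <- if (length(rankings) == 1) {
    r <- rankings[[1]]
    r$rank <- rank(r$rank, ties.method = "first")
    r
  } else aggregate_rankings(rankings)
  if (!is.null(top_k)) top_frac <- NULL
  threshold_network(cons, top_k = top_k, top_frac = top_frac)
}
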