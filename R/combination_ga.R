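# Five-objective selection of drug combinations with NSGA-II.
#
# Objectives per subset S (2 <= |S| <= max_size):
#   f1 number of drugs (minimized by default),
#   f2 mean pairwise mechanism-of-action (HIM) distance (maximized),
#   f3 mean pairwise chemical-structure distance (maximized),
#   f4 coverage of the disease network by the union of targets (maximized),
#   f5 mean pairwise target shortest-path distance (maximized).
# Every direction can be flipped in the configuration.

ga_default_config <- function() {
  list(pop_size = 100L, generations = 200L, p_crossover = 0.9,
       p_mut_bit = NA_real_, max_size = 4L, seed = 1L,
       directions = c(f1_size = "min", f2_moa = "max", f3_structure = "max",
                      f4_coverage = "max", f5_target_dist = "max"),
       xi = 1, structure_metric = "tanimoto")
}

#' Assemble the precomputed inputs for combination search
#'
#' @param moa symmetric drug-drug HIM distance matrix ([moa_matrix()]).
#' @param chem symmetric drug-drug chemical distance matrix (one of the
#'   [chem_matrices()] outputs).
#' @param net igraph disease network.
#' @param drugs a `drug_library` (targets are read from it).
#' @param unreachable_policy passed to [target_pair_distance()];
#'   unreachable-only pairs score 0 in f5.
#' @return list used by [evaluate_objectives()] and [run_ga()], containing
#'   the candidate id vector, the two distance matrices, the per-drug
#'   target pair-distance matrix and per-drug action node sets.
#' @export
ga_precompute <- function(moa, chem, net, drugs,
                          unreachable_policy = "exclude") {
  ids <- Reduce(intersect, list(rownames(moa), rownames(chem), names(drugs)))
  ids <- sort(ids)
  if (length(ids) < 3) stop("need >= 3 candidate drugs present in all inputs")
  topo <- topology_report(net, drugs[ids],
                          unreachable_policy = unreachable_policy)
  tdist <- topo$pair_distance
  tdist[is.nan(tdist)] <- 0
  vn <- igraph::V(net)$name
  action_sets <- lapply(ids, function(i) {
    tv <- intersect(drugs[[i]]$targets, vn)
    if (length(tv) == 0) return(integer(0))
    nb <- unique(unlist(lapply(tv, function(t)
      as.integer(igraph::neighbors(net, t)))))
    unique(c(match(tv, vn), nb))
  })
  names(action_sets) <- ids
  list(ids = ids, moa = moa[ids, ids], chem = chem[ids, ids],
       tdist = tdist[ids, ids], action_sets = action_sets,
       n_nodes = length(vn))
}

#' Evaluate the five objectives of a drug subset
#'
#' @param subset character vector of >= 2 drug ids.
#' @param precomp output of [ga_precompute()].
#' @return named numeric vector `f1_size`, `f2_moa`, `f3_structure`,
#'   `f4_coverage`, `f5_target_dist` (raw orientation: f1 is a count, the
#'   rest are distances/fractions).
#' @export
evaluate_objectives <- function(subset, precomp) {
  missing <- setdiff(subset, precomp$ids)
  if (length(missing) > 0)
    stop("drugs missing from precomputed inputs: ",
         paste(missing, collapse = ", "))
  if (length(subset) < 2) stop("subset must have >= 2 drugs")
  pairs <- combn(subset, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  td <- precomp$tdist[cbind(i, j)]
  cov_nodes <- unique(unlist(precomp$action_sets[subset]))
  c(f1_size = length(subset),
    f2_moa = mean(precomp$moa[cbind(i, j)]),
    f3_structure = mean(precomp$chem[cbind(i, j)]),
    f4_coverage = length(cov_nodes) / precomp$n_nodes,
    f5_target_dist = mean(td[!is.na(td)], na.rm = TRUE))
}

# Map raw objectives to the canonical all-minimize orientation.
canonical_objectives <- function(obj, directions) {
  sgn <- ifelse(directions[names(obj)] == "max", -1, 1)
  unname(sgn) * obj
}

#' Pareto dominance (canonical all-minimize orientation)
#'
#' @param v1,v2 numeric objective vectors already in minimize orientation.
#' @return `TRUE` iff `v1` is no worse everywhere and strictly better
#'   somewhere.
#' @export
dominates <- function(v1, v2) {
  all(v1 <= v2) && any(v1 < v2)
}

#' Non-dominated subset of a set of objective vectors
#'
#' @param objs numeric matrix, one row per solution, canonical minimize
#'   orientation.
#' @return logical vector marking the non-dominated rows.
#' @export
pareto_front <- function(objs) {
  n <- nrow(objs)
  nd <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!nd[i]) next
    le <- objs <= matrix(objs[i, ], n, ncol(objs), byrow = TRUE)
    lt <- objs < matrix(objs[i, ], n, ncol(objs), byrow = TRUE)
    dom_i <- rowSums(le) == ncol(objs) & rowSums(lt) > 0
    dom_i[i] <- FALSE
    if (any(dom_i & nd)) nd[i] <- FALSE
  }
  nd
}

# Fast non-dominated sorting: returns integer front rank per row (1 = best).
nds_ranks <- function(objs) {
  n <- nrow(objs)
  ranks <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    idx <- which(remaining)
    nd <- pareto_front(objs[idx, , drop = FALSE])
    ranks[idx[nd]] <- r
    remaining[idx[nd]] <- FALSE
  }
  ranks
}

# Crowding distance within one front.
crowding <- function(objs) {
  n <- nrow(objs)
  if (n <= 2) return(rep(Inf, n))
  cd <- rep(0, n)
  for (k in seq_len(ncol(objs))) {
    o <- objs[, k]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    cd[ord[c(1, n)]] <- Inf
    if (rng > 0)
      cd[ord[2:(n - 1)]] <- cd[ord[2:(n - 1)]] +
        (o[ord[3:n]] - o[ord[1:(n - 2)]]) / rng
  }
  cd
}

repair_chromosome <- function(bits, max_size) {
  on <- which(bits)
  if (length(on) < 2) {
    add <- sample(which(!bits), 2 - length(on))
    bits[add] <- TRUE
  } else if (length(on) > max_size) {
    drop <- sample(on, length(on) - max_size)
    bits[drop] <- FALSE
  }
  bits
}

#' Search for Pareto-optimal drug combinations with NSGA-II
#'
#' Binary-membership chromosomes over the candidate drug list, repaired to
#' subset sizes in `[2, max_size]`; fast non-dominated sorting with
#' crowding distance, binary tournament selection, uniform crossover and
#' per-bit flip mutation. Fully reproducible given `config$seed`.
#'
#' @param precomp output of [ga_precompute()].
#' @param config named list overriding the defaults
#'   (`pop_size = 100`, `generations = 200`, `p_crossover = 0.9`,
#'   `p_mut_bit = 1/L`, `max_size = 4`, `seed = 1`, objective
#'   `directions`).
#' @return list of `pareto_solution` objects (subset, raw `objectives`,
#'   `rank = 1`, `crowding`), deduplicated by subset and sorted by subset
#'   label.
#' @export
run_ga <- function(precomp, config = list()) {
  cfg <- utils::modifyList(ga_default_config(), config)
  L <- length(precomp$ids)
  if (cfg$max_size < 2) stop("max_size must be >= 2")
  if (L < cfg$max_size + 1) stop("need more candidate drugs than max_size")
  if (is.na(cfg$p_mut_bit)) cfg$p_mut_bit <- 1 / L
  set.seed(cfg$seed)

  eval_cache <- new.env(parent = emptyenv())
  eval_bits <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    v <- eval_cache[[key]]
    if (is.null(v)) {
      v <- evaluate_objectives(precomp$ids[bits], precomp)
      eval_cache[[key]] <- v
    }
    v
  }

  new_random <- function() {
    bits <- rep(FALSE, L)
    k <- sample(2:cfg$max_size, 1)
    bits[sample(L, k)] <- TRUE
    bits
  }
  pop <- lapply(seq_len(cfg$pop_size), function(i) new_random())
  raw <- t(vapply(pop, eval_bits, numeric(5)))
  can <- t(apply(raw, 1, canonical_objectives, directions = cfg$directions))

  for (gen in seq_len(cfg$generations)) {
    ranks <- nds_ranks(can)
    cd <- rep(0, length(pop))
    for (r in unique(ranks)) {
      idx <- which(ranks == r)
      cd[idx] <- crowding(can[idx, , drop = FALSE])
    }
    tournament <- function() {
      cand <- sample(length(pop), 2)
      a <- cand[1]; b <- cand[2]
      if (ranks[a] < ranks[b]) a
      else if (ranks[b] < ranks[a]) b
      else if (cd[a] >= cd[b]) a else b
    }
    offspring <- vector("list", cfg$pop_size)
    i <- 1L
    while (i <= cfg$pop_size) {
      p1 <- pop[[tournament()]]; p2 <- pop[[tournament()]]
      if (stats::runif(1) < cfg$p_crossover) {
        mask <- stats::runif(L) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i > cfg$pop_size) break
        flip <- stats::runif(L) < cfg$p_mut_bit
        child <- xor(child, flip)
        offspring[[i]] <- repair_chromosome(child, cfg$max_size)
        i <- i + 1L
      }
    }
    off_raw <- t(vapply(offspring, eval_bits, numeric(5)))
    off_can <- t(apply(off_raw, 1, canonical_objectives,
                       directions = cfg$directions))
    all_pop <- c(pop, offspring)
    all_raw <- rbind(raw, off_raw)
    all_can <- rbind(can, off_can)
    all_ranks <- nds_ranks(all_can)
    keep <- integer(0)
    for (r in sort(unique(all_ranks))) {
      idx <- which(all_ranks == r)
      if (length(keep) + length(idx) <= cfg$pop_size) {
        keep <- c(keep, idx)
      } else {
        cdr <- crowding(all_can[idx, , drop = FALSE])
        need <- cfg$pop_size - length(keep)
        keep <- c(keep, idx[order(-cdr)][seq_len(need)])
        break
      }
    }
    pop <- all_pop[keep]
    raw <- all_raw[keep, , drop = FALSE]
    can <- all_can[keep, , drop = FALSE]
  }

  ranks <- nds_ranks(can)
  first <- which(ranks == 1L)
  subsets <- vapply(pop[first], function(b)
    paste(sort(precomp$ids[b]), collapse = ";"), character(1))
  keep <- first[!duplicated(subsets)]
  ord <- order(subsets[!duplicated(subsets)])
  keep <- keep[ord]
  cdv <- crowding(can[keep, , drop = FALSE])
  sols <- lapply(seq_along(keep), function(k) {
    b <- pop[[keep[k]]]
    obj <- raw[keep[k], ]
    names(obj) <- colnames(raw) <- c("f1_size", "f2_moa", "f3_structure",
                                     "f4_coverage", "f5_target_dist")
    structure(list(subset = sort(precomp$ids[b]), objectives = obj,
                   rank = 1L, crowding = cdv[k]),
              class = "pareto_solution")
  })
  attr(sols, "config") <- cfg
  sols
}

#' @export
print.pareto_solution <- function(x, ...) {
  cat(sprintf("{%s}  %s\n", paste(x$subset, collapse = ", "),
              paste(sprintf("%s=%.4g", names(x$objectives), x$objectives),
                    collapse = " ")))
  invisible(x)
}

#' Summarize a Pareto front by combination size
#'
#' @param solutions list of `pareto_solution`s.
#' @return list with `counts` (named integer vector: combination size ->
#'   number of front members) and `table` (one row per solution with its
#'   five objectives).
#' @export
report_front <- function(solutions) {
  if (length(solutions) == 0)
    return(list(counts = integer(0),
                table = data.frame(subset = character(0))))
  sizes <- vapply(solutions, function(s) length(s$subset), integer(1))
  counts <- table(factor(sizes, levels = sort(unique(sizes))))
  tab <- do.call(rbind, lapply(solutions, function(s)
    data.frame(subset = paste(s$subset, collapse = ";"),
               t(s$objectives), stringsAsFactors = FALSE)))
  list(counts = setNames(as.integer(counts), names(counts)), table = tab)
}
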