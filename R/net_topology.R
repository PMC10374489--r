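# Topological drug properties on the disease network: area of action
# (targets plus their direct interactors, as a fraction of the network)
# and mean shortest-path distance between the target sets of drug pairs.

#' Area of action of a target set on a network
#'
#' Fraction of network nodes covered by the in-network targets and their
#' direct interactors: `|(T intersect V) union N(T intersect V)| / |V|`.
#' Targets absent from the network are ignored (their count is attached as
#' attribute `targets_outside`).
#'
#' @param net igraph disease network.
#' @param targets character vector of target gene symbols.
#' @return fraction in \[0, 1\].
#' @export
area_of_action <- function(net, targets) {
  nv <- igraph::vcount(net)
  if (nv == 0) stop("network is empty")
  vn <- igraph::V(net)$name
  tv <- intersect(unique(targets), vn)
  outside <- length(setdiff(unique(targets), vn))
  if (length(tv) == 0)
    return(structure(0, targets_outside = outside))
  nb <- unique(unlist(lapply(tv, function(t)
    igraph::V(net)$name[as.integer(igraph::neighbors(net, t))])))
  structure(length(union(tv, nb)) / nv, targets_outside = outside)
}

#' Mean shortest-path distance between two drugs' target sets
#'
#' Mean unweighted shortest-path length over all cross pairs
#' `(t_a, t_b)` with `t_a` in drug A's in-network targets and `t_b` in
#' drug B's; a shared target contributes a zero-length pair. Within-drug
#' pairs are never counted.
#'
#' @param net igraph disease network.
#' @param targets_a,targets_b target gene sets of the two drugs.
#' @param unreachable_policy `"exclude"` (default) drops pairs in
#'   different components from the mean; `"penalize"` scores them as
#'   `|V|`.
#' @param weighted if `TRUE`, use `1 - weight` edge lengths instead of
#'   hop counts.
#' @return mean distance (numeric scalar) with attribute
#'   `unreachable_pairs`; `NaN` when every pair is excluded.
#' @export
target_pair_distance <- function(net, targets_a, targets_b,
                                 unreachable_policy = c("exclude", "penalize"),
                                 weighted = FALSE) {
  unreachable_policy <- match.arg(unreachable_policy)
  vn <- igraph::V(net)$name
  ta <- intersect(unique(targets_a), vn)
  tb <- intersect(unique(targets_b), vn)
  if (length(ta) == 0) stop("drug A has no target in the network")
  if (length(tb) == 0) stop("drug B has no target in the network")
  w <- if (weighted) 1 - igraph::E(net)$weight else NA
  d <- igraph::distances(net, v = ta, to = tb, weights = w)
  vals <- as.numeric(d)
  unreach <- sum(!is.finite(vals))
  if (unreachable_policy == "penalize") {
    vals[!is.finite(vals)] <- length(vn)
  } else {
    vals <- vals[is.finite(vals)]
  }
  structure(if (length(vals) == 0) NaN else mean(vals),
            unreachable_pairs = unreach)
}

#' Coverage of the disease network by a drug combination
#'
#' Area of action of the union of the member drugs' targets; shared
#' targets are not double-counted.
#'
#' @param net igraph disease network.
#' @param drugs a `drug_library` (or list of drug records).
#' @param subset character vector of drug ids; default all.
#' @return fraction in \[0, 1\].
#' @export
combination_coverage <- function(net, drugs, subset = names(drugs)) {
  if (length(subset) == 0) stop("subset must be non-empty")
  missing <- setdiff(subset, names(drugs))
  if (length(missing) > 0)
    stop("unknown drugs: ", paste(missing, collapse = ", "))
  all_targets <- unique(unlist(lapply(drugs[subset], `[[`, "targets")))
  as.numeric(area_of_action(net, all_targets))
}

#' Batch topology report for a drug library
#'
#' @param net igraph disease network.
#' @param drugs a `drug_library`.
#' @param unreachable_policy passed to [target_pair_distance()].
#' @return list with `per_drug` (data.frame: drug_id, targets_in_network,
#'   targets_outside, area_of_action), `pair_distance` (symmetric matrix;
#'   `NA` where a drug has no in-network target), `unreachable_pairs`
#'   (matrix of excluded-pair counts) and `errors` (character vector of
#'   per-drug problems; the batch continues past them).
#' @export
topology_report <- function(net, drugs,
                            unreachable_policy = c("exclude", "penalize")) {
  unreachable_policy <- match.arg(unreachable_policy)
  ids <- names(drugs)
  vn <- igraph::V(net)$name
  in_net <- lapply(drugs, function(d) intersect(unique(d$targets), vn))
  aoa <- vapply(ids, function(i) as.numeric(area_of_action(net, drugs[[i]]$targets)),
                numeric(1))
  per_drug <- data.frame(
    drug_id = ids,
    targets_in_network = vapply(in_net, length, integer(1)),
    targets_outside = vapply(ids, function(i)
      length(setdiff(unique(drugs[[i]]$targets), vn)), integer(1)),
    area_of_action = aoa,
    stringsAsFactors = FALSE)
  errors <- sprintf("drug %s has no target in the network",
                    ids[per_drug$targets_in_network == 0])
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  u <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    if (length(in_net[[i]]) == 0 || length(in_net[[j]]) == 0) next
    d <- target_pair_distance(net, in_net[[i]], in_net[[j]],
                              unreachable_policy = unreachable_policy)
    m[i, j] <- m[j, i] <- as.numeric(d)
    u[i, j] <- u[j, i] <- attr(d, "unreachable_pairs")
  }
  list(per_drug = per_drug, pair_distance = m, unreachable_pairs = u,
       errors = errors)
}
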