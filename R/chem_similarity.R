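# Chemical structure comparison: canonical SMILES (OpenBabel via
# ChemmineOB), circular (Morgan/ECFP-type) fingerprints with Tanimoto
# similarity, maximal common connected substructure, and Levenshtein
# distance on canonical SMILES.

.mol_cache <- new.env(parent = emptyenv())

#' Canonicalize a SMILES string
#'
#' Round-trips the string through OpenBabel's canonical SMILES writer, so
#' any two encodings of the same molecule map to the same string and the
#' operation is idempotent.
#'
#' @param smiles SMILES string.
#' @return canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                               paste0(smiles, " m"))),
    error = function(e) "")
  out <- trimws(sub("[ \t].*$", "", out))
  if (!nzchar(out)) stop("unparseable SMILES: '", smiles, "'")
  out
}

# Molecular graph of the canonical form: atoms (element, aromatic flag,
# estimated implicit H), bonds (order; 0 codes aromatic). Cached.
mol_graph <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (!is.null(.mol_cache[[can]])) return(.mol_cache[[can]])
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(m = can)))[[1]]
  # fixed-width V2000 fields; ChemmineR's accessors mis-parse 0-bond mols
  txt <- strsplit(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(can, " m"))),
    "\n", fixed = TRUE)[[1]]
  n <- as.integer(substr(txt[4], 1, 3))
  nb <- as.integer(substr(txt[4], 4, 6))
  element <- vapply(seq_len(n), function(i)
    trimws(substr(txt[4 + i], 32, 34)), character(1))
  bonds <- if (nb == 0) matrix(numeric(0), 0, 3) else
    t(vapply(seq_len(nb), function(r) {
      ln <- txt[4 + n + r]
      c(as.integer(substr(ln, 1, 3)), as.integer(substr(ln, 4, 6)),
        as.integer(substr(ln, 7, 9)))
    }, numeric(3)))

  aromatic <- rep(FALSE, n)
  arom_bond <- matrix(FALSE, n, n)
  rng <- tryCatch(suppressWarnings(ChemmineR::rings(sdf, arom = TRUE)),
                  error = function(e) NULL)
  if (!is.null(rng) && length(rng$RINGS) > 0) {
    for (ri in seq_along(rng$RINGS)) {
      if (!isTRUE(rng$AROMATIC[[ri]])) next
      idx <- as.integer(sub("^.*_", "", rng$RINGS[[ri]]))
      aromatic[idx] <- TRUE
      cyc <- c(idx, idx[1])
      for (k in seq_len(length(idx)))
        arom_bond[cyc[k], cyc[k + 1]] <- arom_bond[cyc[k + 1], cyc[k]] <- TRUE
    }
  }

  blab <- matrix(NA_real_, n, n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      lab <- if (arom_bond[i, j]) 0 else bonds[r, 3]
      blab[i, j] <- blab[j, i] <- lab
    }
  }
  degree <- rowSums(!is.na(blab))
  bond_sum <- rowSums(ifelse(is.na(blab), 0, ifelse(blab == 0, 1.5, blab)))
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
               I = 1, B = 3)
  h_count <- pmax(0, round(ifelse(element %in% names(valence),
                                  valence[element], 0) - bond_sum))
  g <- list(n = n, element = element, aromatic = aromatic, blab = blab,
            degree = degree, bond_sum = bond_sum, h_count = h_count,
            canonical = can)
  .mol_cache[[can]] <- g
  g
}

# 32-bit FNV-1a over a character string, in double arithmetic.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 65536
    h <- (h - lo) + bitwXor(as.integer(lo), as.integer(b))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  h
}

#' Circular (Morgan/ECFP-type) fingerprint
#'
#' Iteratively hashes each atom's neighborhood out to `radius` bonds,
#' starting from atom invariants (element, heavy degree, total bond order,
#' estimated hydrogen count, aromaticity), and folds all environment
#' identifiers into `n_bits` positions. Computed on the canonical form, so
#' the fingerprint is invariant to the input SMILES encoding.
#'
#' @param smiles SMILES string.
#' @param radius neighborhood radius in bonds (default 2, the ECFP4
#'   equivalent).
#' @param n_bits folded fingerprint length (default 1024).
#' @param drug_id optional identifier carried in the result.
#' @return list of class `fingerprint`: sorted unique `bits` (0-based),
#'   `n_bits`, `radius`, `drug_id`.
#' @export
ecfp <- function(smiles, radius = 2, n_bits = 1024, drug_id = NA_character_) {
  if (radius < 0) stop("radius must be >= 0")
  if (n_bits < 8) stop("n_bits must be >= 8")
  g <- mol_graph(smiles)
  ids <- vapply(seq_len(g$n), function(a)
    fnv1a(paste(g$element[a], g$degree[a], g$bond_sum[a], g$h_count[a],
                as.integer(g$aromatic[a]), sep = ":")), numeric(1))
  all_ids <- ids
  if (radius > 0 && g$n > 1) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(g$n), function(a) {
        nb <- which(!is.na(g$blab[a, ]))
        if (length(nb) == 0) return(ids[a])
        pairs <- sprintf("%g,%.0f", g$blab[a, nb], ids[nb])
        fnv1a(paste(c(sprintf("r%d", r), sprintf("%.0f", ids[a]),
                      sort(pairs)), collapse = "|"))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  structure(list(bits = sort(unique(as.integer(all_ids %% n_bits))),
                 n_bits = as.integer(n_bits), radius = as.integer(radius),
                 drug_id = drug_id),
            class = "fingerprint")
}

#' Tanimoto similarity between fingerprints
#'
#' `|A intersect B| / |A union B|`; both-empty bit sets count as identical
#' objects (similarity 1).
#'
#' @param fp1,fp2 [ecfp()] fingerprints of equal `n_bits`.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp1, fp2) {
  if (fp1$n_bits != fp2$n_bits)
    stop("fingerprints have different n_bits: ", fp1$n_bits, " vs ", fp2$n_bits)
  u <- length(union(fp1$bits, fp2$bits))
  if (u == 0) return(1)
  length(intersect(fp1$bits, fp2$bits)) / u
}

#' Maximal common connected substructure
#'
#' Branch-and-bound search (McGregor style) for the largest connected
#' common subgraph under atom matching by element + aromaticity and bond
#' matching by order (aromatic bonds match only aromatic bonds). The
#' search is seeded from every compatible atom pair; a per-call wall-clock
#' budget turns long searches into flagged approximate results.
#'
#' @param smiles1,smiles2 SMILES strings.
#' @param timeout_s wall-clock budget in seconds (default 10).
#' @return list with `atom_count`, `bond_count`, `similarity`
#'   (`atoms_mcs / (atoms1 + atoms2 - atoms_mcs)`) and `approximate`
#'   (TRUE when the budget expired before the search completed).
#' @export
mcs <- function(smiles1, smiles2, timeout_s = 10) {
  g1 <- mol_graph(smiles1)
  g2 <- mol_graph(smiles2)
  lab1 <- paste(g1$element, as.integer(g1$aromatic))
  lab2 <- paste(g2$element, as.integer(g2$aromatic))
  deadline <- proc.time()[3] + timeout_s

  st <- new.env(parent = emptyenv())
  st$best <- 0L; st$best_bonds <- 0L; st$timed_out <- FALSE

  count_bonds <- function(m1, m2) {
    if (length(m1) < 2) return(0L)
    cnt <- 0L
    for (a in seq_along(m1)) for (b in seq_len(a - 1L)) {
      l1 <- g1$blab[m1[a], m1[b]]; l2 <- g2$blab[m2[a], m2[b]]
      if (!is.na(l1) && !is.na(l2) && l1 == l2) cnt <- cnt + 1L
    }
    cnt
  }

  rec <- function(m1, m2, excluded) {
    if (proc.time()[3] > deadline) { st$timed_out <- TRUE; return() }
    size <- length(m1)
    if (size > st$best) {
      st$best <- size
      st$best_bonds <- count_bonds(m1, m2)
    } else if (size == st$best) {
      bc <- count_bonds(m1, m2)
      if (bc > st$best_bonds) st$best_bonds <- bc
    }
    rem1 <- g1$n - size - length(excluded)
    rem2 <- g2$n - size
    if (size + min(rem1, rem2) <= st$best) return()
    # frontier: unmapped, unexcluded atoms of g1 bonded to the mapped set
    cand1 <- setdiff(which(vapply(seq_len(g1$n), function(a)
      any(!is.na(g1$blab[a, m1])), logical(1))), c(m1, excluded))
    if (length(cand1) == 0) return()
    a <- cand1[1]
    for (b in setdiff(seq_len(g2$n), m2)) {
      if (lab1[a] != lab2[b]) next
      ok <- FALSE
      for (k in seq_along(m1)) {
        l1 <- g1$blab[a, m1[k]]; l2 <- g2$blab[b, m2[k]]
        if (!is.na(l1) && !is.na(l2) && l1 == l2) { ok <- TRUE; break }
      }
      if (ok) rec(c(m1, a), c(m2, b), excluded)
      if (st$timed_out) return()
    }
    rec(m1, m2, c(excluded, a))
  }

  for (a0 in seq_len(g1$n)) {
    if (st$timed_out) break
    for (b0 in seq_len(g2$n)) {
      if (lab1[a0] != lab2[b0]) next
      rec(a0, b0, seq_len(a0 - 1L))
      if (st$timed_out) break
    }
  }
  atoms <- st$best
  list(atom_count = atoms, bond_count = st$best_bonds,
       similarity = atoms / (g1$n + g2$n - atoms),
       approximate = st$timed_out)
}

#' Levenshtein edit distance between two strings
#'
#' Unit-cost insertions, deletions and substitutions (via [utils::adist()]).
#' This operates on raw strings; for molecules use [smiles_levenshtein()],
#' which canonicalizes first.
#'
#' @param a,b character strings.
#' @return integer edit distance.
#' @export
levenshtein <- function(a, b) {
  as.integer(adist(a, b)[1, 1])
}

#' Levenshtein distance between canonical SMILES
#'
#' Both inputs are canonicalized before comparison so the distance does
#' not depend on the arbitrary input encoding.
#'
#' @param smiles1,smiles2 SMILES strings.
#' @param normalize divide by the longer canonical string length
#'   (default TRUE), giving a value in \[0, 1\].
#' @return numeric distance.
#' @export
smiles_levenshtein <- function(smiles1, smiles2, normalize = TRUE) {
  c1 <- canonical_smiles(smiles1)
  c2 <- canonical_smiles(smiles2)
  d <- levenshtein(c1, c2)
  if (!normalize) return(d)
  L <- max(nchar(c1), nchar(c2))
  if (L == 0) 0 else d / L
}

#' All pairwise chemical distance matrices for a drug library
#'
#' Drugs without a usable SMILES are excluded (reported via [message()]).
#'
#' @param drugs a `drug_library`.
#' @param radius,n_bits [ecfp()] parameters.
#' @param mcs_timeout_s per-pair MCS budget in seconds.
#' @return list of symmetric zero-diagonal distance matrices `tanimoto`
#'   (1 - Tanimoto similarity), `mcs` (1 - MCS similarity), `levenshtein`
#'   (normalized canonical-SMILES edit distance), plus `excluded` ids.
#' @export
chem_matrices <- function(drugs, radius = 2, n_bits = 1024,
                          mcs_timeout_s = 10) {
  has_smi <- vapply(drugs, function(d) !is.na(d$smiles), logical(1))
  excluded <- names(drugs)[!has_smi]
  if (length(excluded) > 0)
    message("chem_matrices: excluded drugs without SMILES: ",
            paste(excluded, collapse = ", "))
  ids <- names(drugs)[has_smi]
  if (length(ids) < 2) stop("need >= 2 drugs with SMILES")
  fps <- lapply(ids, function(i) ecfp(drugs[[i]]$smiles, radius, n_bits, i))
  names(fps) <- ids
  mk <- function() matrix(0, length(ids), length(ids),
                          dimnames = list(ids, ids))
  tan <- mk(); mc <- mk(); lev <- mk()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    si <- drugs[[ids[i]]]$smiles; sj <- drugs[[ids[j]]]$smiles
    tan[i, j] <- tan[j, i] <- 1 - tanimoto(fps[[i]], fps[[j]])
    mc[i, j] <- mc[j, i] <- 1 - mcs(si, sj, timeout_s = mcs_timeout_s)$similarity
    lev[i, j] <- lev[j, i] <- smiles_levenshtein(si, sj)
  }
  list(tanimoto = tan, mcs = mc, levenshtein = lev, excluded = excluded)
}
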