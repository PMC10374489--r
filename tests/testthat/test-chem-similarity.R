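test_that("canonicalization unifies encodings and is idempotent", {
  expect_equal(canonical_smiles("OCC"), canonical_smiles("CCO"))
  can <- canonical_smiles("CC(=O)OC1=CC=CC=C1C(=O)O")
  expect_equal(canonical_smiles(can), can)
  expect_error(canonical_smiles("not_a_molecule"), "unparseable")
})

test_that("fingerprints are invariant to SMILES encoding", {
  f1 <- ecfp("CCO"); f2 <- ecfp("OCC")
  expect_equal(f1$bits, f2$bits)
  expect_equal(tanimoto(f1, f2), 1)

  # benzene vs cyclohexane: aromatic vs aliphatic environments must differ
  fb <- ecfp("c1ccccc1"); fc <- ecfp("C1CCCCC1")
  expect_false(identical(fb$bits, fc$bits))
  expect_lt(tanimoto(fb, fc), 1)

  expect_error(ecfp("CCO", radius = -1), "radius")
  expect_error(ecfp("CCO", n_bits = 4), "n_bits")
})

test_that("radius-0 ethanol fingerprint has one bit per atom-invariant class", {
  # heavy atoms of CCO: terminal CH3, middle CH2 (bonded to O), OH
  # -> three distinct invariant classes, no folding collision at 1024 bits
  fp <- ecfp("CCO", radius = 0, n_bits = 1024)
  expect_length(fp$bits, 3)
  expect_true(all(fp$bits >= 0 & fp$bits < 1024))
})

test_that("Tanimoto similarity follows the set formula", {
  mk <- function(bits) structure(list(bits = bits, n_bits = 1024L,
                                      radius = 2L, drug_id = NA),
                                 class = "fingerprint")
  expect_equal(tanimoto(mk(c(1, 2, 3)), mk(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(mk(1:5), mk(1:5)), 1)
  expect_equal(tanimoto(mk(1:3), mk(7:9)), 0)
  expect_equal(tanimoto(mk(integer(0)), mk(integer(0))), 1)
  bad <- mk(1:3); bad$n_bits <- 512L
  expect_error(tanimoto(mk(1:3), bad), "n_bits")
})

test_that("MCS handles the forced cases and matches brute-force enumeration", {
  self <- mcs("CC(=O)OC1=CC=CC=C1C(=O)O", "CC(=O)OC1=CC=CC=C1C(=O)O")
  expect_equal(self$atom_count, 13)  # aspirin heavy atoms
  expect_equal(self$similarity, 1)

  m <- mcs("C", "CC")
  expect_equal(m$atom_count, 1)
  expect_equal(m$similarity, 0.5)

  # ethanol vs propanol against an independent exhaustive oracle
  lab_eth <- c("C", "C", "O")
  b_eth <- matrix(NA, 3, 3); b_eth[1, 2] <- b_eth[2, 1] <- 1
  b_eth[2, 3] <- b_eth[3, 2] <- 1
  lab_pro <- c("C", "C", "C", "O")
  b_pro <- matrix(NA, 4, 4)
  for (i in 1:3) b_pro[i, i + 1] <- b_pro[i + 1, i] <- 1
  atoms <- oracle_mcs_atoms(lab_eth, b_eth, lab_pro, b_pro)
  got <- mcs("CCO", "CCCO")
  expect_equal(got$atom_count, atoms)
  expect_equal(got$similarity, atoms / (3 + 4 - atoms))
  expect_false(got$approximate)
})

test_that("Levenshtein distance matches the recursive definition and is a metric", {
  expect_equal(levenshtein("kitten", "sitting"), 3)
  expect_equal(levenshtein("kitten", "sitting"),
               oracle_levenshtein("kitten", "sitting"))
  expect_equal(levenshtein("", "CCO"), 3)
  expect_equal(levenshtein("abc", "abc"), 0)

  set.seed(17)
  rand_str <- function() paste(sample(letters[1:4], sample(0:8, 1),
                                      replace = TRUE), collapse = "")
  for (rep in 1:25) {
    a <- rand_str(); b <- rand_str(); c0 <- rand_str()
    dab <- levenshtein(a, b)
    expect_equal(dab, oracle_levenshtein(a, b))
    expect_equal(dab, levenshtein(b, a))
    expect_equal(levenshtein(a, a), 0)
    expect_lte(dab, levenshtein(a, c0) + levenshtein(c0, b))
  }
})

test_that("SMILES Levenshtein canonicalizes before comparing", {
  expect_equal(smiles_levenshtein("CCO", "OCC"), 0)
  d <- smiles_levenshtein("CCO", "CCCO", normalize = FALSE)
  expect_equal(d, 1)
  dn <- smiles_levenshtein("CCO", "CCCO")
  expect_equal(dn, 1 / 4)
})

test_that("chemical distances ignore the input encoding of a molecule", {
  forms <- list(aspirin = c("CC(=O)OC1=CC=CC=C1C(=O)O",
                            "O=C(C)Oc1ccccc1C(=O)O"),
                caffeine = c("CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
                             "Cn1cnc2c1c(=O)n(C)c(=O)n2C"))
  for (nm in names(forms)) {
    f <- forms[[nm]]
    expect_equal(canonical_smiles(f[1]), canonical_smiles(f[2]), info = nm)
    expect_equal(tanimoto(ecfp(f[1]), ecfp(f[2])), 1, info = nm)
    expect_equal(smiles_levenshtein(f[1], f[2]), 0, info = nm)
    expect_equal(mcs(f[1], f[2])$similarity, 1, info = nm)
  }
})

test_that("pairwise chemical matrices are symmetric and element-wise correct", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsmiles\ttargets",
               "ethanol\tCCO\tG1",
               "ethanol2\tOCC\tG2",
               "benzene\tc1ccccc1\tG3",
               "no_structure\t\tG4"), p)
  lib <- read_drug_library(p)
  expect_message(mats <- chem_matrices(lib), "no_structure")
  for (m in mats[c("tanimoto", "mcs", "levenshtein")]) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 3))
    expect_true(all(m >= 0 & m <= 1))
  }
  # duplicate molecule under two encodings: zero distance everywhere
  expect_equal(mats$tanimoto["ethanol", "ethanol2"], 0)
  expect_equal(mats$mcs["ethanol", "ethanol2"], 0)
  expect_equal(mats$levenshtein["ethanol", "ethanol2"], 0)
  # element-wise agreement with the pairwise operations
  expect_equal(mats$tanimoto["ethanol", "benzene"],
               1 - tanimoto(ecfp("CCO"), ecfp("c1ccccc1")))
  expect_equal(mats$levenshtein["ethanol", "benzene"],
               smiles_levenshtein("CCO", "c1ccccc1"))

  lib1 <- lib["ethanol"]
  class(lib1) <- "drug_library"
  expect_error(chem_matrices(lib1), ">= 2 drugs")
})

test_that("openbabel canonicalization agrees with an independent toolkit on identity", {
  pairs <- list(c("CCO", "OCC"), c("c1ccccc1", "C1=CC=CC=C1"),
                c("CC(=O)OC1=CC=CC=C1C(=O)O", "O=C(C)Oc1ccccc1C(=O)O"))
  py <- Sys.which("python")
  if (!nzchar(py)) succeed("python unavailable; covered by invariance tests")
  if (nzchar(py)) {
    code <- paste(
      "from rdkit import Chem",
      "import sys",
      "for line in sys.stdin:",
      "    a, b = line.split()",
      "    ca = Chem.MolToSmiles(Chem.MolFromSmiles(a))",
      "    cb = Chem.MolToSmiles(Chem.MolFromSmiles(b))",
      "    print(int(ca == cb))", sep = "\n")
    inp <- vapply(pairs, paste, character(1), collapse = " ")
    out <- tryCatch(system2(py, c("-c", shQuote(code)), input = inp,
                            stdout = TRUE, stderr = FALSE),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(out) && length(out) == length(pairs)) {
      expect_equal(out, rep("1", length(pairs)))
      for (pr in pairs)
        expect_equal(canonical_smiles(pr[1]), canonical_smiles(pr[2]))
    } else {
      succeed("rdkit oracle unavailable; covered by invariance tests")
    }
  }
})
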