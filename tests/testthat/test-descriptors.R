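shed_of <- function(counts_by_bin) {
  m <- matrix(0, 21, 11, dimnames = list(feature_pairs(),
                                         c(as.character(1:10), "gt")))
  m["ACC:DON", seq_along(counts_by_bin)] <- counts_by_bin
  compute_shed(m)[["ACC:DON"]]
}

test_that("FPD counts featured-atom pairs into the right distance bins", {
  # ethane-1,2-diol: exactly two featured atoms (both O, {ACC, DON}), 3 bonds
  mol <- parse_smiles("OCCO")
  fa <- assign_features(mol)
  fpd <- compute_fpd(mol, fa, Dmax = 10)
  expect_equal(unname(fpd["ACC:ACC", "3"]), 1)
  expect_equal(unname(fpd["ACC:DON", "3"]), 2)
  expect_equal(unname(fpd["DON:DON", "3"]), 1)
  expect_equal(sum(fpd), 4)
  # single-bin rows have zero entropy
  expect_true(all(compute_shed(fpd) == 0))
  # normalization: non-zero rows sum to 1
  fpdn <- compute_fpd(mol, fa, Dmax = 10, normalize = TRUE)
  rs <- rowSums(fpdn)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
})

test_that("SHED entropies match the closed forms", {
  expect_equal(shed_of(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shed_of(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shed_of(5), 0)
  expect_equal(shed_of(numeric(0)), 0)
})

test_that("SHED is bounded and non-decreasing under flattening", {
  for (s in FIXTURE_SMILES) {
    mol <- parse_smiles(s)
    fpd <- compute_fpd(mol, assign_features(mol), Dmax = 10)
    h <- compute_shed(fpd)
    expect_true(all(h >= 0), label = s)
    expect_true(all(h <= log(11) + 1e-12), label = s)
  }
  expect_lte(shed_of(c(4, 0)), shed_of(c(3, 1)))
  expect_lte(shed_of(c(3, 1)), shed_of(c(2, 2)))
})

test_that("PHRAG enumerates typed shortest-path fragments", {
  mol <- parse_smiles("OCCO")
  fa <- assign_features(mol)
  ph <- compute_phrag(mol, fa, L = 5)
  expect_equal(length(ph), 1)
  expect_equal(unname(ph[1]), 1L)
  expect_equal(names(ph), "ACC+DON-x-x-ACC+DON")
  # too short a window excludes the pair
  expect_length(compute_phrag(mol, fa, L = 3), 0)
})

test_that("descriptor similarities are 1 on self and 0 on disjoint input", {
  m1 <- parse_smiles(FIXTURE_SMILES[["paracetamol"]])
  m2 <- parse_smiles(FIXTURE_SMILES[["hexane"]])
  f1 <- assign_features(m1); f2 <- assign_features(m2)
  p1 <- compute_phrag(m1, f1); p2 <- compute_phrag(m2, f2)
  expect_equal(phrag_similarity(p1, p1), 1)
  expect_equal(phrag_similarity(p1, p2), 0) # HYD-only vs polar fragments
  d1 <- compute_fpd(m1, f1); d2 <- compute_fpd(m2, f2)
  expect_equal(fpd_similarity(d1, d1), 1)
  s1 <- compute_shed(d1)
  expect_equal(shed_similarity(s1, s1), 1)
  expect_lt(shed_similarity(s1, compute_shed(d2)), 1)
})

test_that("molecules with fewer than two featured atoms degrade gracefully", {
  mol <- parse_smiles("C") # single HYD atom
  fa <- assign_features(mol)
  expect_equal(sum(compute_fpd(mol, fa)), 0)
  expect_true(all(compute_shed(compute_fpd(mol, fa)) == 0))
  expect_length(compute_phrag(mol, fa), 0)
})

test_that("descriptors are invariant to atom reindexing", {
  set.seed(19)
  for (s in FIXTURE_SMILES[c("ibuprofen", "paracetamol", "nicotine",
                             "benzamide", "glycine")]) {
    m <- parse_smiles(s)
    fa <- assign_features(m)
    ref_fpd <- compute_fpd(m, fa)
    ref_ph <- compute_phrag(m, fa)
    for (k in 1:2) {
      mr <- parse_smiles(rewrite_smiles(m))
      far <- assign_features(mr)
      expect_equal(unclass(compute_fpd(mr, far)), unclass(ref_fpd), label = s)
      expect_identical(sort(names(compute_phrag(mr, far))),
                       sort(names(ref_ph)), label = s)
    }
  }
})
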