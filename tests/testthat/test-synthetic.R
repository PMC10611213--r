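test_that("the generator honors the spec arithmetic", {
  spec <- synthetic_spec(seed = 17, n_targets = 5, actives_per_target = 20,
                         overlap_fraction = 0)
  gen <- gen_reference_library(spec)
  expect_equal(nrow(gen$library$compounds), 100)
  expect_equal(nrow(gen$library$targets), 5)
  sets <- ligand_sets(gen$library, cutoff = 0)
  expect_true(all(vapply(sets, length, 1L) == 20))
  # zero overlap: ligand sets pairwise disjoint
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(sets[[i]], sets[[j]]), 0)
  }
  expect_equal(nrow(check_library_integrity(gen$library)), 0)
  # ground truth referentially consistent with the library
  expect_true(all(gen$ground_truth$compound_id %in%
                    gen$library$compounds$compound_id))
  expect_true(all(gen$ground_truth$target_id %in%
                    gen$library$targets$target_id))
})

test_that("generation is byte-deterministic under the seed", {
  spec <- synthetic_spec(seed = 99, n_targets = 3, actives_per_target = 8)
  g1 <- gen_reference_library(spec)
  g2 <- gen_reference_library(spec)
  expect_identical(g1$library$compounds$smiles, g2$library$compounds$smiles)
  expect_equal(as.data.frame(g1$library$activities),
               as.data.frame(g2$library$activities))
  q1 <- gen_query_drugs(spec, g1)
  q2 <- gen_query_drugs(spec, g2)
  expect_identical(q1, q2)
  a1 <- gen_expression_atlas(spec)
  a2 <- gen_expression_atlas(spec)
  expect_identical(a1$atlases[["human"]]$mat, a2$atlases[["human"]]$mat)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_fixtures(spec, d1)
  write_synthetic_fixtures(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every generated structure parses and overlap plants second targets", {
  spec <- synthetic_spec(seed = 4, n_targets = 4, actives_per_target = 10,
                         overlap_fraction = 0.2)
  gen <- gen_reference_library(spec)
  for (s in gen$library$compounds$smiles) expect_no_error(parse_smiles(s))
  per_cpd <- table(gen$ground_truth$compound_id)
  expect_gt(sum(per_cpd == 2), 0)
})

test_that("held-out queries are absent from the library and correctly labelled", {
  spec <- synthetic_spec(seed = 17, n_targets = 4, actives_per_target = 10)
  gen <- gen_reference_library(spec)
  q <- gen_query_drugs(spec, gen, held_out_fraction = 0.5)
  expect_equal(nrow(q), 4 * 5)
  lib_canon <- gen$library$compounds$canonical
  for (i in seq_len(nrow(q))) {
    expect_false(canonical_smiles(parse_smiles(q$smiles[i])) %in% lib_canon)
  }
  expect_true(all(q$true_target %in% gen$library$targets$target_id))
  expect_error(gen_query_drugs(spec, gen, held_out_fraction = 0),
               class = "offtarget_config_error")
  expect_error(gen_query_drugs(spec, gen, held_out_fraction = 1.5),
               class = "offtarget_config_error")
})

test_that("planted atlas genes dominate their home tissue", {
  spec <- synthetic_spec(seed = 8)
  atl <- gen_expression_atlas(spec)
  blocks <- atl$blocks
  mat <- atl$atlases[["human"]]$mat
  for (i in seq_len(nrow(blocks))) {
    row <- mat[blocks$gene[i], ]
    expect_equal(names(which.max(row)), blocks$home_tissue[i])
    expect_gt(max(row), 3) # planted mean 5 against background ~0.5
  }
  # near-zero noise pins the background at 0.5
  quiet <- gen_expression_atlas(synthetic_spec(seed = 8, noise_sd = 1e-9))
  bg <- quiet$atlases[["human"]]$mat[paste0("BG", sprintf("%03d", 1:5)), ]
  expect_equal(unname(as.vector(bg)), rep(0.5, length(bg)), tolerance = 1e-6)
})

test_that("spec validation rejects impossible requests", {
  expect_error(synthetic_spec(overlap_fraction = 2),
               class = "offtarget_config_error")
  expect_error(synthetic_spec(actives_per_target = 500),
               class = "offtarget_config_error")
})
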