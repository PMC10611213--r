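test_that("SIM scores a library ligand against its own target at 1.0", {
  lib <- toy_library()
  res <- predict_sim("Nc1ccc(C)cc1", lib, "PHRAG")
  expect_equal(res$score[res$target_id == "TA"], 1.0)
  # analog of TA chemistry only: must rank TA above TB in every channel
  for (d in c("PHRAG", "FPD", "SHED")) {
    r <- predict_sim("Nc1ccc(Br)cc1", lib, d, floor = 0)
    sa <- r$score[r$target_id == "TA"]
    sb <- r$score[r$target_id == "TB"]
    expect_gt(sa, if (length(sb) == 0) 0 else sb)
  }
})

test_that("SIM requires the descriptor cache and honors the floor", {
  raw <- make_reference_library(tibble::tibble(
    compound_id = "c1", smiles = "CCO", target_id = "T1",
    target_class = "GPCR", activity_type = "IC50", value_nm = 10,
    moa = "inhibitor", source = "t"))
  expect_error(predict_sim("CCO", raw, "PHRAG"),
               class = "offtarget_state_error")
  lib <- toy_library()
  all_rows <- predict_sim("Nc1ccc(Br)cc1", lib, "PHRAG", floor = 0)
  floored <- predict_sim("Nc1ccc(Br)cc1", lib, "PHRAG", floor = 0.99)
  expect_lte(nrow(floored), nrow(all_rows))
  expect_true(all(floored$score >= 0.99))
})

test_that("SEA raw score equals brute-force pair enumeration", {
  lib <- bench()$lib
  ids <- lib$compounds$compound_id
  fps <- lapply(ids, function(cid) offtarget:::compound_descriptor(lib, cid)$fp)
  names(fps) <- ids
  set.seed(31)
  for (k in 1:5) {
    a <- sample(ids, 6); b <- sample(ids, 9)
    brute <- 0
    for (x in a) for (y in b) {
      tc <- tanimoto(fps[[x]], fps[[y]])
      if (tc >= 0.57) brute <- brute + tc
    }
    expect_equal(sea_raw_score(fps[a], fps[b], 0.57), brute, tolerance = 1e-12)
  }
})

test_that("the extreme-value transform matches its closed form", {
  gamma <- 0.57721566490153286
  expect_equal(sea_pvalue(0), 1 - exp(-exp(-gamma)), tolerance = 1e-12)
  expect_equal(sea_pvalue(0), 0.4296, tolerance = 1e-4)
  z <- seq(-3, 6, by = 0.5)
  expect_true(all(diff(sea_pvalue(z)) < 0))
  expect_true(all(sea_pvalue(z) >= 0 & sea_pvalue(z) <= 1))
})

test_that("the SEA background fit is seeded, monotone, and validated", {
  lib <- bench()$lib
  b1 <- fit_sea_background(lib, seed = 5, reps = 30, set_sizes = c(2, 4, 8))
  b2 <- fit_sea_background(lib, seed = 5, reps = 30, set_sizes = c(2, 4, 8))
  expect_identical(b1$draws, b2$draws)
  expect_identical(tidy(b1), tidy(b2))
  n <- c(4, 16, 64)
  expect_true(all(diff(offtarget:::sea_mu(b1, n)) >= 0))
  expect_error(fit_sea_background(lib, reps = 10),
               class = "offtarget_config_error")
  expect_error(fit_sea_background(lib, set_sizes = 4),
               class = "offtarget_config_error")
})

test_that("an unreachable tau yields an all-zero background", {
  lib <- toy_library()
  bg <- fit_sea_background(lib, tau = 1.01, reps = 30, set_sizes = c(2, 3))
  expect_true(all(bg$draws$rs == 0))
  expect_equal(offtarget:::sea_mu(bg, 10), 0, tolerance = 1e-9)
  expect_error(offtarget:::sea_sigma(bg, 10), class = "offtarget_state_error")
})

test_that("predict_sea reports one-term sums and sorted p-values", {
  lib <- toy_library()
  bg <- fit_sea_background(lib, tau = 0.57, reps = 30, set_sizes = c(2, 3))
  res <- predict_sea("Nc1ccc(C)cc1", lib, bg)
  expect_true(all(diff(res$p) >= 0))
  expect_true(all(res$rs >= 0))
  expect_equal(res$score, 1 - res$p)
  # no pair reaches tau: raw score must be exactly 0
  far <- predict_sea("c1ccsc1", lib, bg)
  expect_true(all(far$rs == 0))
  expect_error(predict_sea("CCO", lib, bg, tau = 0.9),
               class = "offtarget_config_error")
})

test_that("SAS recovers a planted pharmacophore motif and scores by containment", {
  lib <- toy_library()
  sig <- suppressWarnings(build_sas_signatures(lib, f = 0.8))
  expect_true("TA" %in% names(sig$signatures))
  # all TA actives share the aniline DON/POS-on-aromatic motif
  expect_true(any(grepl("ARO", sig$signatures$TA) &
                    grepl("DON", sig$signatures$TA)))
  full <- predict_sas("Nc1ccc(C)cc1", sig)
  expect_equal(full$score[full$target_id == "TA"], 1.0)
  none <- predict_sas("O", sig) # no featured pairs, hence no fragments
  expect_true(all(none$score == 0))
  expect_true(all(tidy(sig)$n_fragments >= 0))
})

test_that("SAS skips targets with fewer than three actives, with a warning", {
  rows <- tibble::tibble(
    compound_id = c("a1", "a2", "a3", "b1"),
    smiles = c("Nc1ccccc1", "Nc1ccc(C)cc1", "Nc1ccc(O)cc1", "CCO"),
    target_id = c("TA", "TA", "TA", "TB"),
    target_class = c("GPCR", "GPCR", "GPCR", "Enzyme"),
    activity_type = "IC50", value_nm = 10, moa = "inhibitor", source = "t")
  lib <- precompute_descriptors(make_reference_library(rows))
  expect_warning(sig <- build_sas_signatures(lib), "TB")
  expect_false("TB" %in% names(sig$signatures))
})

test_that("SAR separates disjoint chemical families", {
  lib <- toy_library()
  # suppressWarnings: glmnet warns about tiny class sizes on the toy library
  models <- suppressWarnings(suppressMessages(train_sar(lib, seed = 2)))
  own <- predict_sar("Nc1ccc(C)cc1", lib, models)
  expect_gt(own$score[own$target_id == "TA"], 0.5)
  expect_gt(own$score[own$target_id == "TA"],
            own$score[own$target_id == "TB"])
  other <- predict_sar("CCCCCO", lib, models)
  expect_gt(other$score[other$target_id == "TB"],
            other$score[other$target_id == "TA"])
})

test_that("MLM votes map to scores in thirds with a majority consensus", {
  b <- bench()
  q <- b$queries[1, ]
  res <- predict_mlm(q$smiles, b$lib, b$predictors$mlm)
  expect_true(all(res$score %in% c(0, 1 / 3, 2 / 3, 1)))
  expect_equal(res$consensus_positive, res$score >= 2 / 3)
  # unanimity configuration tightens the consensus
  res3 <- predict_mlm(q$smiles, b$lib, b$predictors$mlm, min_votes = 3)
  expect_equal(res3$consensus_positive, res3$score == 1)
  votes <- vapply(res$evidence, function(e) jsonlite::fromJSON(e)$votes, 1)
  expect_equal(unname(votes) / 3, res$score)
})

test_that("MLM skips targets with too few positives", {
  lib <- toy_library() # 5 actives per target < 10
  fit <- suppressMessages(train_mlm(lib, seed = 1, min_pos = 10))
  expect_length(fit$bundles, 0)
  expect_setequal(fit$skipped, c("TA", "TB"))
})

test_that("XPI matches its set formula and is symmetric with unit diagonal", {
  overlap_rows <- tibble::tibble(
    compound_id = c(sprintf("x%d", 1:4), sprintf("y%d", 1:8), "x1"),
    smiles = c("CCO", "CCN", "CCC", "CCCC",
               "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC", "CCCCCCCCC",
               "CCCCCCCCCC", "CCCCCCCCCCC", "CCCCCCCCCCCC", "CCO"),
    target_id = c(rep("TA", 4), rep("TB", 8), "TB"),
    target_class = c(rep("GPCR", 4), rep("Enzyme", 9)),
    activity_type = "IC50", value_nm = 10, moa = "inhibitor", source = "t")
  lib <- make_reference_library(overlap_rows)
  xpi <- compute_xpi(lib)
  expect_equal(unname(xpi["TA", "TB"]), 1 / 4) # overlap 1, min(|4|, |8+1|)...
  expect_equal(xpi, t(xpi))
  expect_equal(unname(diag(xpi)), c(1, 1))

  seeds <- tibble::tibble(target_id = "TA", score = 0.8)
  prop <- predict_xpi(seeds, xpi, floor = 0.1)
  expect_equal(prop$score[prop$target_id == "TA"], 0.8)
  expect_equal(prop$score[prop$target_id == "TB"], 0.8 * 0.25)
})

test_that("every method score lies in [0, 1] with evidence attached", {
  b <- bench()
  scores <- predict_targets(b$queries[1:2, ], b$predictors)
  expect_true(all(scores$score >= 0 & scores$score <= 1))
  expect_true(all(nzchar(scores$evidence[scores$score > 0])))
  expect_setequal(unique(scores$method),
                  c("SAS", "SAR", "SIM", "SEA", "MLM", "XPI"))
})
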