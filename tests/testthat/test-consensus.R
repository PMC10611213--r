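test_that("the certainty rule and normalization bound the pseudo-score", {
  # training-set member with matching mechanism of action: certainty
  expect_equal(aggregate_pseudo_score(
    c(SAS = 0, SAR = 0, SIM = 0, SEA = 0, MLM = 0, XPI = 0),
    in_training_set = TRUE, same_moa = TRUE), 1.0)
  # nothing predicts, not in the training set
  expect_equal(aggregate_pseudo_score(numeric(0)), 0)
  # unanimous methods saturate the score
  expect_equal(aggregate_pseudo_score(
    setNames(rep(1, 6), c("SAS", "SAR", "SIM", "SEA", "MLM", "XPI"))), 1.0)
  # most-methods rule: five significant methods force certainty
  expect_equal(aggregate_pseudo_score(
    c(SAS = 0.6, SAR = 0.6, SIM = 0.6, SEA = 0.6, MLM = 0.6)), 1.0)
  expect_lt(aggregate_pseudo_score(
    c(SAS = 0.6, SAR = 0.6, SIM = 0.6, SEA = 0.6, MLM = 0.6),
    majority_n = Inf), 1.0)
  # absent methods count as zero with full weight
  expect_equal(aggregate_pseudo_score(c(SIM = 0.9)), 0.9 / 6)
  expect_error(aggregate_pseudo_score(c(SIM = 1), weights = c(SIM = -1)),
               class = "offtarget_config_error")
})

test_that("the pseudo-score is monotone in every method score", {
  set.seed(23)
  methods <- c("SAS", "SAR", "SIM", "SEA", "MLM", "XPI")
  for (k in 1:50) {
    sc <- setNames(runif(6), methods)
    s0 <- aggregate_pseudo_score(sc)
    m <- sample(methods, 1)
    sc2 <- sc
    sc2[m] <- min(1, sc[m] + runif(1, 0, 1 - sc[m]))
    expect_gte(aggregate_pseudo_score(sc2), s0)
  }
})

test_that("confirmation marking uses existence and the max-potency rule", {
  preds <- tibble::tibble(drug_id = c("d1", "d2", "d3"),
                          target_id = c("T1", "T1", "T2"),
                          pseudo_score = 0.9)
  acts <- tibble::tibble(
    compound_id = c("d1", "d3", "d3"), target_id = c("T1", "T2", "T2"),
    value_nm = c(50, 200, 20))
  out <- mark_confirmed(preds, acts)
  expect_equal(out$status,
               c("confirmed_in_vitro", "predicted_unconfirmed",
                 "confirmed_in_vitro"))
  expect_equal(out$best_pactivity[1], to_pactivity(50), tolerance = 1e-9)
  expect_equal(out$best_pactivity[3], to_pactivity(20), tolerance = 1e-9)
  expect_equal(round(out$best_pactivity[c(1, 3)], 2), c(7.30, 7.70))
})

test_that("class summaries reproduce printed floor-percents and conserve totals", {
  ref <- reference_class_counts()
  # rebuild a prediction table with the printed counts and summarize it
  preds <- purrr::pmap(ref, function(target_class, total_predicted,
                                     predicted_unconfirmed, confirmed, ...) {
    tibble::tibble(
      drug_id = "d", target_id = target_class, target_class = target_class,
      status = rep(c("confirmed_in_vitro", "predicted_unconfirmed"),
                   c(confirmed, predicted_unconfirmed)))
  }) %>% dplyr::bind_rows()
  got <- summarize_by_class(preds)
  expect_equal(nrow(got), 9)
  merged <- dplyr::left_join(ref, got, by = "target_class")
  expect_equal(merged$pct_confirmed, merged$printed_pct)
  expect_equal(merged$total_predicted.y, merged$total_predicted.x)
  expect_equal(sum(got$total_predicted), nrow(preds))
  expect_error(summarize_by_class(tibble::tibble(
    target_class = "Martian", status = "confirmed_in_vitro")),
    class = "offtarget_value_error")
})

test_that("affinity bins follow the stated half-open boundaries", {
  preds <- tibble::tibble(
    drug_id = "d", target_id = c("a", "b", "c"),
    status = "confirmed_in_vitro", best_pactivity = c(7.1, 8.5, 9.2))
  bins <- affinity_bins(preds)
  expect_equal(bins$n_lt_100nM, 3)
  expect_equal(bins$n_10_1nM, 1)
  expect_equal(bins$n_lt_1nM, 1)
  empty <- affinity_bins(preds[0, ])
  expect_true(all(unlist(empty) == 0))
  # nesting
  expect_lte(bins$n_lt_1nM, bins$n_lt_1nM + bins$n_10_1nM)
  expect_lte(bins$n_lt_1nM + bins$n_10_1nM, bins$n_lt_100nM)
})

test_that("binning equals a brute-force recount on shuffled input", {
  set.seed(3)
  p <- tibble::tibble(
    drug_id = "d", target_id = as.character(1:200),
    status = sample(c("confirmed_in_vitro", "predicted_unconfirmed"),
                    200, replace = TRUE),
    best_pactivity = runif(200, 5, 10))
  p$best_pactivity[p$status != "confirmed_in_vitro"] <- NA
  bins <- affinity_bins(p[sample(nrow(p)), ])
  conf <- p$best_pactivity[p$status == "confirmed_in_vitro"]
  brute <- c(sum(conf > 7), sum(conf >= 8 & conf < 9), sum(conf >= 9))
  expect_equal(c(bins$n_lt_100nM, bins$n_10_1nM, bins$n_lt_1nM), brute)
})

test_that("per-drug statistics report float, floor and round means", {
  p <- tibble::tibble(drug_id = rep(sprintf("d%04d", 1:1471),
                                    length.out = 10648),
                      target_id = "t")
  st <- per_drug_stats(p)
  expect_equal(st$n_drugs, 1471)
  expect_equal(st$mean_per_drug_floor, 7)
  empty <- per_drug_stats(p[0, ])
  expect_equal(empty$n_interactions, 0)
  expect_equal(empty$mean_per_drug, 0)
})

test_that("consensus predictions wire methods, flags and classes together", {
  b <- bench()
  scores <- predict_targets(b$queries[1:3, ], b$predictors)
  cons <- consensus_predictions(scores, b$lib)
  expect_true(all(cons$pseudo_score >= 0 & cons$pseudo_score <= 1))
  expect_equal(cons$significant, cons$pseudo_score >= 0.55)
  expect_true(all(cons$status == "predicted_unconfirmed"))
  expect_true(all(cons$target_class %in% target_classes()))
  # library member with matching mechanism of action scores exactly 1
  member <- b$lib$activities[1, ]
  mscores <- predict_targets(
    tibble::tibble(compound_id = member$compound_id,
                   smiles = b$lib$compounds$smiles[
                     b$lib$compounds$compound_id == member$compound_id]),
    b$predictors)
  mcons <- consensus_predictions(
    mscores, b$lib,
    query_moa = tibble::tibble(query_id = member$compound_id,
                               target_id = member$target_id,
                               moa = member$moa))
  expect_equal(
    mcons$pseudo_score[mcons$target_id == member$target_id], 1.0)
})
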