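test_that("pCmax conversion matches printed exposure values", {
  expect_equal(compute_pcmax(0.0520), 7.28)
  expect_equal(compute_pcmax(1.0), 6.00)
  expect_equal(compute_pcmax(13.1), 4.88)
  expect_equal(compute_pcmax(0.0056), 8.25)
  expect_error(compute_pcmax(0), class = "offtarget_value_error")
  expect_error(compute_pcmax(-1), class = "offtarget_value_error")
})

test_that("exposure flags compare potency and exposure on the p-scale", {
  f <- exposure_flags(7.5, 7.28)
  expect_true(f$sub_um); expect_true(f$engaged)
  expect_equal(f$margin, 0.22, tolerance = 1e-9)
  f2 <- exposure_flags(6.5, 7.28)
  expect_true(f2$sub_um); expect_false(f2$engaged)
  f3 <- exposure_flags(5.0, 6.0)
  expect_false(f3$sub_um)
  # boundary: exactly 6.0 is not sub-micromolar (strict >)
  expect_false(exposure_flags(6.0, 5.0)$sub_um)
})

test_that("the verdict rules fire as stated", {
  expect_equal(as.character(
    three_criteria_verdict(TRUE, TRUE, 0.9, 7.2)$verdict), "pursue")
  expect_equal(as.character(
    three_criteria_verdict(TRUE, TRUE, 0.9, 5.5)$verdict), "optimize_potency")
  expect_equal(as.character(
    three_criteria_verdict(TRUE, TRUE, 0.50, 7.2)$verdict), "deprioritize")
  # boundary: a pseudo-score of exactly 0.55 fails the strict criterion
  expect_equal(as.character(
    three_criteria_verdict(TRUE, TRUE, 0.55, 7.2)$verdict), "deprioritize")
})

test_that("the verdict partition is exhaustive and mutually exclusive", {
  lattice <- expand.grid(evidence = c(TRUE, FALSE), expressed = c(TRUE, FALSE),
                         strong_score = c(TRUE, FALSE), potent = c(TRUE, FALSE))
  v <- three_criteria_verdict(
    lattice$evidence, lattice$expressed,
    ifelse(lattice$strong_score, 0.9, 0.3),
    ifelse(lattice$potent, 7.5, 5.0))
  expect_false(any(is.na(v$verdict)))
  expect_equal(nrow(v), 16)
  # pursue iff all four; optimize iff criteria without potency
  expect_equal(v$verdict == "pursue",
               lattice$evidence & lattice$expressed & lattice$strong_score &
                 lattice$potent)
  expect_equal(v$verdict == "optimize_potency",
               lattice$evidence & lattice$expressed & lattice$strong_score &
                 !lattice$potent)
  expect_true(all(nzchar(v$rationale)))
})

test_that("the safety screen flags the liability panel and only it", {
  preds <- tibble::tibble(drug_id = "d",
                          target_id = c("KCNH2", "EGFR", "HTR2B"))
  out <- safety_liability_screen(preds)
  expect_equal(out$safety_review, c(TRUE, FALSE, TRUE))
  expect_match(attr(out, "caveat"), "binding-only")
  none <- safety_liability_screen(preds, liabilities = character(0))
  expect_false(any(none$safety_review))
})

test_that("triage records join exposure, evidence and expression", {
  preds <- tibble::tibble(
    drug_id = "drugA", target_id = c("T1", "T2", "T3"),
    pseudo_score = c(0.9, 0.9, 0.4),
    best_pactivity = c(7.5, 5.5, 7.0),
    expressed = c(TRUE, TRUE, TRUE))
  exposures <- tibble::tibble(drug_id = "drugA", cmax_um = 0.052)
  evidence <- tibble::tibble(target_id = c("T1", "T2"),
                             disease = "x", source = "lit")
  rec <- triage_records(preds, exposures, evidence)
  expect_equal(nrow(rec), 3)
  expect_equal(unique(rec$pcmax), 7.28)
  expect_equal(as.character(rec$verdict[rec$target_id == "T1"]), "pursue")
  expect_equal(as.character(rec$verdict[rec$target_id == "T2"]),
               "optimize_potency")
  expect_equal(as.character(rec$verdict[rec$target_id == "T3"]),
               "deprioritize")
})

test_that("reports count sub-micromolar off-targets and conserve predictions", {
  preds <- tibble::tibble(
    drug_id = rep(c("d1", "d2"), c(3, 2)),
    target_id = c("T1", "T2", "T3", "T1", "T4"),
    best_pactivity = c(7.1, 6.2, 5.9, 8.0, NA))
  exposures <- tibble::tibble(drug_id = "d1", cmax_um = 1.0,
                              intended_targets = "T9")
  rep_tbl <- suppressWarnings(build_report(preds, exposures))
  d1 <- rep_tbl[rep_tbl$drug_id == "d1", ]
  expect_equal(d1$n_sub_um, 2L)
  expect_equal(d1$pcmax, 6.00)
  expect_equal(d1$intended_targets, "T9")
  d2 <- rep_tbl[rep_tbl$drug_id == "d2", ]
  expect_true(is.na(d2$pcmax)) # no exposure record
  expect_equal(sum(rep_tbl$n_predicted), nrow(preds))
  expect_warning(build_report(preds, exposures), "no exposure record")
  # drug with exposure but no predictions: empty row plus warning
  lonely <- suppressWarnings(
    build_report(preds[0, ], tibble::tibble(drug_id = "d9", cmax_um = 2)))
  expect_equal(lonely$n_predicted, 0L)
})
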