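# Exposure-aware repurposing triage
#
# pCmax = -log10(Cmax in mol/L) = 6 - log10(Cmax in uM), rounded half away
# from zero to 2 decimals. A prediction is worth pursuing when all three
# repurposing criteria hold (literature evidence, tissue expression,
# pseudo-score > 0.55) and the measured potency is sub-micromolar
# (pIC50 > 6.0); criteria met with weak potency routes to potency
# optimization; anything else is deprioritized.

#' Convert Cmax (uM, free plasma) to pCmax
#'
#' @param cmax_um positive Cmax value(s) in micromolar.
#' @return pCmax rounded to 2 decimals (half away from zero).
#' @examples
#' compute_pcmax(0.052) # 7.28
#' compute_pcmax(13.1)  # 4.88
#' @export
compute_pcmax <- function(cmax_um) {
  if (any(!is.finite(cmax_um) | cmax_um <= 0)) {
    stop_offtarget("Cmax must be positive and finite", "offtarget_value_error")
  }
  round_half_away(6 - log10(cmax_um), 2)
}

#' Potency/exposure comparison flags
#'
#' @param pactivity measured pIC50 (pActivity).
#' @param pcmax clinical exposure as pCmax.
#' @return Tibble `sub_um` (pIC50 > 6.0), `engaged` (pIC50 >= pCmax, i.e.
#'   IC50 at or below Cmax), `margin` (pIC50 - pCmax, signed).
#' @export
exposure_flags <- function(pactivity, pcmax) {
  tibble(sub_um = pactivity > 6.0,
         engaged = pactivity >= pcmax,
         margin = pactivity - pcmax)
}

#' Three-criteria repurposing verdict
#'
#' Criteria: (1) literature evidence links the target to a therapeutic
#' outcome, (2) the target is expressed in the relevant tissues, (3) the
#' consensus pseudo-score exceeds 0.55. All three plus sub-micromolar
#' measured potency = `pursue`; all three with weak potency =
#' `optimize_potency`; otherwise `deprioritize`.
#'
#' @param evidence_present,expressed logical criterion flags (vectorized).
#' @param pseudo_score consensus pseudo-score.
#' @param pactivity measured pIC50 (`NA` treated as weak potency).
#' @param score_threshold pseudo-score cutoff (default 0.55, strict `>`).
#' @return Tibble `criteria_met`, `sub_um`, `verdict` (factor), `rationale`.
#' @export
three_criteria_verdict <- function(evidence_present, expressed, pseudo_score,
                                   pactivity, score_threshold = 0.55) {
  score_ok <- pseudo_score > score_threshold
  expressed <- !is.na(expressed) & expressed
  evidence_present <- !is.na(evidence_present) & evidence_present
  criteria <- evidence_present & expressed & score_ok
  sub_um <- !is.na(pactivity) & pactivity > 6.0
  verdict <- dplyr::case_when(
    criteria & sub_um ~ "pursue",
    criteria ~ "optimize_potency",
    TRUE ~ "deprioritize"
  )
  rationale <- paste0(
    "evidence=", ifelse(evidence_present, "yes", "no"),
    "; expression=", ifelse(expressed, "yes", "no"),
    "; score>", score_threshold, "=", ifelse(score_ok, "yes", "no"),
    "; subuM=", ifelse(sub_um, "yes", "no"))
  tibble(criteria_met = criteria, sub_um = sub_um,
         verdict = factor(verdict,
                          levels = c("pursue", "optimize_potency",
                                     "deprioritize")),
         rationale = rationale)
}

#' Assemble full triage records
#'
#' Joins predictions with exposure, evidence and expression annotations and
#' applies the three-criteria verdict per (drug, target).
#'
#' @param predictions consensus predictions (after [mark_confirmed()] and
#'   [filter_by_expression()]; must carry `pseudo_score`, `best_pactivity`,
#'   `expressed`).
#' @param exposures tibble `drug_id`, `cmax_um` (+ optional
#'   `intended_targets`, `dose_note`).
#' @param evidence tibble `target_id`, `disease`, `source` (presence of a
#'   row = evidence flag).
#' @param score_threshold pseudo-score cutoff (default 0.55).
#' @return Tibble of triage records, one per prediction, with `pcmax`,
#'   `pic50`, exposure flags, criteria flags, `verdict` and `rationale`.
#' @export
triage_records <- function(predictions, exposures, evidence = NULL,
                           score_threshold = 0.55) {
  exp_tbl <- exposures %>%
    mutate(pcmax = compute_pcmax(.data$cmax_um)) %>%
    select("drug_id", "cmax_um", "pcmax")
  out <- predictions %>%
    left_join(exp_tbl, by = "drug_id") %>%
    mutate(evidence_present = if (is.null(evidence)) FALSE
           else .data$target_id %in% evidence$target_id[nzchar(evidence$source)])
  flags <- exposure_flags(out$best_pactivity, out$pcmax)
  v <- three_criteria_verdict(out$evidence_present, out$expressed,
                              out$pseudo_score, out$best_pactivity,
                              score_threshold)
  bind_cols(out, select(flags, "engaged", "margin"), v) %>%
    arrange(.data$drug_id, .data$verdict, desc(.data$margin), .data$target_id)
}

#' Flag predictions against known safety-liability targets
#'
#' Binding predictions against the liability panel (default: serotonin 2B
#' receptor HTR2B, PPAR-gamma PPARG, hERG channel KCNH2, and KIT) are
#' flagged for safety review. Binding-only caveat: the pipeline does not
#' predict functional direction (agonism vs antagonism), so flags request
#' review rather than rejection.
#'
#' @param predictions tibble with `target_id` (gene symbols or target ids).
#' @param liabilities character vector of liability targets.
#' @return `predictions` with logical `safety_review` column; the caveat is
#'   attached as attribute `caveat`.
#' @export
safety_liability_screen <- function(predictions,
                                    liabilities = c("HTR2B", "PPARG",
                                                    "KCNH2", "KIT")) {
  gene <- if ("gene" %in% names(predictions)) predictions$gene
          else predictions$target_id
  out <- mutate(predictions,
                safety_review = .data$target_id %in% liabilities |
                  gene %in% liabilities)
  attr(out, "caveat") <-
    "binding-only: functional direction (agonist/antagonist) is not predicted"
  out
}

#' Per-drug triage report (exposure-table style)
#'
#' One row per drug: intended targets, Cmax, pCmax, the count of off-targets
#' with measured pIC50 > 6.0, and the key off-targets ranked by exposure
#' margin (descending) then target id. Drugs without an exposure record get
#' a blank pCmax and a warning.
#'
#' @param predictions consensus predictions with `best_pactivity`.
#' @param exposures tibble `drug_id`, `cmax_um`, optional `intended_targets`.
#' @param max_key number of key off-targets listed (default 10).
#' @return Tibble, one row per drug in `exposures` (plus predicted drugs
#'   missing from it).
#' @export
build_report <- function(predictions, exposures, max_key = 10) {
  drugs <- union(exposures$drug_id, unique(predictions$drug_id))
  rows <- purrr::map(sort(drugs), function(d) {
    ex <- exposures[exposures$drug_id == d, , drop = FALSE]
    if (nrow(ex) == 0) {
      warn(sprintf("no exposure record for drug %s; pCmax left blank", d))
      cmax <- NA_real_; pcmax <- NA_real_; intended <- NA_character_
    } else {
      cmax <- ex$cmax_um[1]
      pcmax <- compute_pcmax(cmax)
      intended <- if ("intended_targets" %in% names(ex)) ex$intended_targets[1]
                  else NA_character_
    }
    pr <- predictions[predictions$drug_id == d, , drop = FALSE]
    if (nrow(pr) == 0) {
      warn(sprintf("no predictions for drug %s; empty report row", d))
      return(tibble(drug_id = d, intended_targets = intended,
                    cmax_um = cmax, pcmax = pcmax, n_predicted = 0L,
                    n_sub_um = 0L, key_off_targets = ""))
    }
    sub <- !is.na(pr$best_pactivity) & pr$best_pactivity > 6.0
    margin <- pr$best_pactivity - pcmax
    ord <- order(-ifelse(is.na(margin), -Inf, margin), pr$target_id)
    keys <- pr$target_id[ord]
    tibble(drug_id = d, intended_targets = intended, cmax_um = cmax,
           pcmax = pcmax, n_predicted = nrow(pr), n_sub_um = sum(sub),
           key_off_targets = paste(utils::head(keys, max_key), collapse = ","))
  })
  bind_rows(rows)
}
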