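# Pseudo-score consensus and class-level summaries
#
# The normalized pseudo-score S aggregates the six method scores with
# configurable weights (equal by default). S = 1.00 is the certainty rule:
# the query is a training-set member with the same mechanism of action, or
# most methods (>= 5 of 6 at or above the significance threshold) agree.
# S >= 0.55 is significant.

PSEUDO_SCORE_THRESHOLD <- 0.55
METHOD_NAMES <- c("SAS", "SAR", "SIM", "SEA", "MLM", "XPI")

#' Aggregate method scores into a pseudo-score
#'
#' @param method_scores named numeric vector of per-method scores (subset of
#'   SAS, SAR, SIM, SEA, MLM, XPI); absent methods contribute 0 with full
#'   weight.
#' @param in_training_set is the molecule part of the reference library with
#'   an annotation for this target?
#' @param same_moa does its annotated mechanism of action match?
#' @param weights named non-negative method weights (default equal).
#' @param majority_n number of methods at or above the significance
#'   threshold that forces S = 1.00 (default 5; `Inf` disables the rule).
#' @param threshold significance threshold (default 0.55).
#' @return Pseudo-score in \[0, 1\].
#' @export
aggregate_pseudo_score <- function(method_scores, in_training_set = FALSE,
                                   same_moa = FALSE, weights = NULL,
                                   majority_n = 5,
                                   threshold = PSEUDO_SCORE_THRESHOLD) {
  weights <- weights %||% setNames(rep(1, 6), METHOD_NAMES)
  if (any(weights < 0)) {
    stop_offtarget("method weights must be non-negative", "offtarget_config_error")
  }
  if (length(method_scores) == 0 && !(in_training_set || same_moa)) {
    return(0)
  }
  if (in_training_set && same_moa) return(1.0)
  full <- setNames(rep(0, 6), METHOD_NAMES)
  known <- intersect(names(method_scores), METHOD_NAMES)
  full[known] <- method_scores[known]
  if (sum(full >= threshold) >= majority_n) return(1.0)
  s <- sum(weights[METHOD_NAMES] * full) / sum(weights[METHOD_NAMES])
  min(max(s, 0), 1)
}

#' Build consensus target predictions from long method scores
#'
#' Pivots the long method-score table to one row per (drug, target), applies
#' the certainty rule against the reference library (training-set membership
#' with matching mechanism of action), and attaches the target class.
#'
#' @param method_scores long tibble from [predict_targets()].
#' @param lib a `reference_library` (certainty-rule lookup and target
#'   classes); `NULL` skips the training-set rule.
#' @param query_moa optional tibble (`query_id`, `target_id`, `moa`) giving
#'   the queries' known mechanisms of action.
#' @param weights,majority_n,threshold see [aggregate_pseudo_score()].
#' @return Tibble of `target_prediction` rows: `drug_id`, `target_id`,
#'   `target_class`, one column per method, `pseudo_score`, `significant`,
#'   `status` (`predicted_unconfirmed` until [mark_confirmed()]),
#'   `best_pactivity`.
#' @export
consensus_predictions <- function(method_scores, lib = NULL, query_moa = NULL,
                                  weights = NULL, majority_n = 5,
                                  threshold = PSEUDO_SCORE_THRESHOLD) {
  if (nrow(method_scores) == 0) {
    return(tibble(drug_id = character(), target_id = character(),
                  target_class = character(), pseudo_score = numeric(),
                  significant = logical(), status = character(),
                  best_pactivity = numeric()))
  }
  wide <- method_scores %>%
    select("query_id", "method", "target_id", "score") %>%
    tidyr::pivot_wider(names_from = "method", values_from = "score",
                       values_fn = max)
  for (m in METHOD_NAMES) if (!m %in% names(wide)) wide[[m]] <- NA_real_

  rows <- purrr::map(seq_len(nrow(wide)), function(i) {
    sc <- unlist(wide[i, METHOD_NAMES])
    sc <- sc[!is.na(sc)]
    in_train <- FALSE; same_moa <- FALSE
    if (!is.null(lib)) {
      acts <- lib$activities[
        lib$activities$compound_id == wide$query_id[i] &
          lib$activities$target_id == wide$target_id[i], , drop = FALSE]
      in_train <- nrow(acts) > 0
      if (in_train && !is.null(query_moa)) {
        qm <- query_moa$moa[query_moa$query_id == wide$query_id[i] &
                              query_moa$target_id == wide$target_id[i]]
        same_moa <- length(qm) > 0 && any(qm %in% acts$moa)
      }
    }
    s <- aggregate_pseudo_score(sc, in_train, same_moa, weights,
                                majority_n, threshold)
    tibble(drug_id = wide$query_id[i], target_id = wide$target_id[i],
           pseudo_score = s)
  })
  out <- bind_rows(rows) %>%
    bind_cols(wide[, METHOD_NAMES]) %>%
    mutate(significant = .data$pseudo_score >= threshold,
           status = "predicted_unconfirmed",
           best_pactivity = NA_real_)
  if (!is.null(lib)) {
    out <- left_join(out,
                     select(lib$targets, "target_id", "target_class"),
                     by = "target_id")
  } else {
    out$target_class <- NA_character_
  }
  out %>%
    select("drug_id", "target_id", "target_class", dplyr::all_of(METHOD_NAMES),
           "pseudo_score", "significant", "status", "best_pactivity") %>%
    arrange(.data$drug_id, desc(.data$pseudo_score), .data$target_id)
}

#' Mark predictions confirmed by measured activities
#'
#' A prediction is confirmed when any activity record exists for its
#' (drug, target) pair; the best (largest) pActivity over matching records
#' is attached.
#'
#' @param predictions tibble from [consensus_predictions()] (or any tibble
#'   with `drug_id`, `target_id`).
#' @param activities tibble with `compound_id`, `target_id` and either
#'   `pactivity` or `value_nm`.
#' @return `predictions` with `status` and `best_pactivity` filled in.
#' @export
mark_confirmed <- function(predictions, activities) {
  if (!"pactivity" %in% names(activities)) {
    activities$pactivity <- to_pactivity(activities$value_nm)
  }
  best <- activities %>%
    group_by(drug_id = .data$compound_id, .data$target_id) %>%
    summarise(best_pactivity = max(.data$pactivity), .groups = "drop")
  predictions %>%
    select(-dplyr::any_of(c("status", "best_pactivity"))) %>%
    left_join(best, by = c("drug_id", "target_id")) %>%
    mutate(status = ifelse(is.na(.data$best_pactivity),
                           "predicted_unconfirmed", "confirmed_in_vitro"))
}

#' Class-level summary of predictions
#'
#' Totals, unconfirmed and confirmed counts per target class, with the
#' percent confirmed as an integer floor - the convention that reproduces
#' published class-level tables (e.g. 3080/3768 = 81.7 prints as 81).
#'
#' @param predictions tibble with `target_class` and `status`.
#' @return Tibble `target_class`, `total_predicted`, `predicted_unconfirmed`,
#'   `confirmed`, `pct_confirmed`; classes with zero predictions are omitted.
#' @export
summarize_by_class <- function(predictions) {
  bad <- setdiff(unique(predictions$target_class), target_classes())
  if (length(bad) > 0) {
    stop_offtarget(sprintf("unknown target class label(s): %s",
                           paste(bad, collapse = ", ")),
                   "offtarget_value_error")
  }
  predictions %>%
    group_by(.data$target_class) %>%
    summarise(
      total_predicted = n(),
      predicted_unconfirmed = sum(.data$status != "confirmed_in_vitro"),
      confirmed = sum(.data$status == "confirmed_in_vitro"),
      .groups = "drop") %>%
    mutate(pct_confirmed = floor_percent(.data$confirmed, .data$total_predicted)) %>%
    arrange(.data$target_class)
}

#' Integer floor of a percentage
#' @param num,den numerator and denominator.
#' @return `floor(100 * num / den)` as integer (0 when `den` is 0).
#' @export
floor_percent <- function(num, den) {
  as.integer(ifelse(den == 0, 0L, floor(100 * num / den)))
}

#' Affinity bins over confirmed predictions
#'
#' Counts confirmed interactions by potency: stronger than 100 nM
#' (pActivity > 7, strict), 10-1 nM (pActivity in \[8, 9)), and stronger
#' than 1 nM (pActivity >= 9). The bins are nested:
#' count(<1 nM) <= count(<=10 nM) <= count(<100 nM).
#'
#' @param predictions tibble with `status` and `best_pactivity`.
#' @return One-row tibble `n_confirmed`, `n_lt_100nM`, `n_10_1nM`, `n_lt_1nM`.
#' @export
affinity_bins <- function(predictions) {
  p <- predictions$best_pactivity[
    predictions$status == "confirmed_in_vitro" &
      !is.na(predictions$best_pactivity)]
  tibble(n_confirmed = length(p),
         n_lt_100nM = sum(p > 7),
         n_10_1nM = sum(p >= 8 & p < 9),
         n_lt_1nM = sum(p >= 9))
}

#' Per-drug interaction statistics
#'
#' @param predictions tibble with `drug_id`.
#' @return One-row tibble `n_drugs`, `n_interactions`, `mean_per_drug`
#'   (float), `mean_per_drug_floor`, `mean_per_drug_round`.
#' @export
per_drug_stats <- function(predictions) {
  n_drugs <- dplyr::n_distinct(predictions$drug_id)
  n_int <- nrow(predictions)
  m <- if (n_drugs == 0) 0 else n_int / n_drugs
  tibble(n_drugs = n_drugs, n_interactions = n_int, mean_per_drug = m,
         mean_per_drug_floor = floor(m),
         mean_per_drug_round = round_half_away(m, 0))
}

#' Write predictions as the documented long TSV
#' @param predictions consensus prediction tibble.
#' @param path output path.
#' @param header_comment optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, header_comment = NULL) {
  write_descriptor_table(predictions, path, header_comment)
}
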