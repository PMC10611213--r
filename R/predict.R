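# Orchestration of the six prediction methods

#' Default prediction configuration
#'
#' Thresholds and method parameters for the full pipeline. All values are
#' configurable; defaults are documented in the methods vignette.
#'
#' @return Named list of settings.
#' @export
default_predict_config <- function() {
  list(
    tau = 0.57,            # SEA Tanimoto threshold
    sim_floor = 0.3,       # SIM minimum reported score
    xpi_floor = 0.2,       # XPI minimum propagated score
    sas_f = 0.8,           # SAS signature frequency fraction
    sas_max_atoms = 8,     # SAS fragment size cap
    sar_lambda = 0.01,     # SAR ridge penalty
    mlm_min_pos = 10,      # MLM minimum positives per target
    mlm_neg_ratio = 3,     # MLM negatives per positive
    mlm_min_votes = 2,     # MLM consensus votes (majority)
    sea_set_sizes = c(2, 4, 8, 16),
    sea_reps = 40,
    methods = c("SAS", "SAR", "SIM", "SEA", "MLM", "XPI")
  )
}

#' Fit every trainable predictor on a reference library
#'
#' Fits the SEA random-set background, the SAS signatures, the SAR models
#' and the MLM classifier bundles, and computes the XPI matrix, under one
#' seed.
#'
#' @param lib a `reference_library`; descriptors are cached here if missing.
#' @param seed master RNG seed.
#' @param config list from [default_predict_config()] (partial lists are
#'   merged over the defaults).
#' @return A `predictor_set` list: `lib` (with descriptors), `background`,
#'   `sas`, `sar`, `mlm`, `xpi`, `seed`, `config`.
#' @export
fit_predictors <- function(lib, seed = 1, config = list()) {
  config <- utils::modifyList(default_predict_config(), config)
  if (is.null(lib$descriptors)) lib <- precompute_descriptors(lib)
  structure(list(
    lib = lib,
    background = fit_sea_background(lib, tau = config$tau,
                                    set_sizes = config$sea_set_sizes,
                                    reps = config$sea_reps, seed = seed),
    sas = suppressWarnings(
      build_sas_signatures(lib, f = config$sas_f,
                           max_atoms = config$sas_max_atoms)),
    sar = train_sar(lib, seed = seed, lambda = config$sar_lambda),
    mlm = train_mlm(lib, seed = seed, min_pos = config$mlm_min_pos,
                    neg_ratio = config$mlm_neg_ratio),
    xpi = compute_xpi(lib),
    seed = seed, config = config
  ), class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("<predictor_set: %d compounds, %d targets, seed=%d>\n",
              nrow(x$lib$compounds), nrow(x$lib$targets), x$seed))
  invisible(x)
}

#' Run all six prediction methods for a set of queries
#'
#' SIM is the per-target maximum over its three descriptor channels; XPI
#' propagates the best per-target score of the other five methods.
#'
#' @param queries tibble with `compound_id` and `smiles`, or a single SMILES
#'   string.
#' @param predictors a `predictor_set` from [fit_predictors()].
#' @return Long tibble: `query_id`, `method`, `target_id`, `score`,
#'   `evidence` (JSON string).
#' @export
predict_targets <- function(queries, predictors) {
  if (is.character(queries)) {
    queries <- tibble(compound_id = "query", smiles = queries)
  }
  lib <- predictors$lib
  cfg <- predictors$config
  out <- purrr::map(seq_len(nrow(queries)), function(i) {
    q <- queries$smiles[i]
    per_method <- list()
    if ("SIM" %in% cfg$methods) {
      sims <- bind_rows(
        predict_sim(q, lib, "PHRAG", floor = cfg$sim_floor),
        predict_sim(q, lib, "FPD", floor = cfg$sim_floor),
        predict_sim(q, lib, "SHED", floor = cfg$sim_floor))
      if (nrow(sims) > 0) {
        per_method$SIM <- sims %>%
          group_by(.data$target_id) %>%
          arrange(desc(.data$score), .by_group = TRUE) %>%
          slice(1) %>% ungroup() %>%
          mutate(method = "SIM")
      }
    }
    if ("SEA" %in% cfg$methods) {
      sea <- predict_sea(q, lib, predictors$background)
      if (nrow(sea) > 0) {
        per_method$SEA <- sea %>%
          mutate(method = "SEA") %>%
          select("method", "target_id", "score", "evidence")
      }
    }
    if ("SAS" %in% cfg$methods) per_method$SAS <- predict_sas(q, predictors$sas)
    if ("SAR" %in% cfg$methods) per_method$SAR <- predict_sar(q, lib, predictors$sar)
    if ("MLM" %in% cfg$methods) {
      per_method$MLM <- predict_mlm(q, lib, predictors$mlm,
                                    min_votes = cfg$mlm_min_votes) %>%
        select("method", "target_id", "score", "evidence")
    }
    scores <- bind_rows(per_method)
    if ("XPI" %in% cfg$methods && nrow(scores) > 0) {
      seeds <- scores %>%
        group_by(.data$target_id) %>%
        summarise(score = max(.data$score), .groups = "drop")
      xpi_rows <- predict_xpi(seeds, predictors$xpi, floor = cfg$xpi_floor)
      scores <- bind_rows(scores, xpi_rows)
    }
    if (nrow(scores) == 0) return(NULL)
    mutate(scores, query_id = queries$compound_id[i], .before = 1)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(query_id = character(), method = character(),
                  target_id = character(), score = numeric(),
                  evidence = character()))
  }
  arrange(res, .data$query_id, .data$method, desc(.data$score), .data$target_id)
}
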