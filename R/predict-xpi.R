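# XPI: cross-pharmacology index
#
# XPI(a, b) = |L_a intersect L_b| / min(|L_a|, |L_b|) over ligand sets; the
# prediction step propagates seed target scores to cross-pharmacology
# partners.

#' Compute the target-by-target cross-pharmacology index
#'
#' @param lib a `reference_library`.
#' @param cutoff ligand-set pActivity cutoff.
#' @return Symmetric numeric matrix (targets x targets) with 1 on the
#'   diagonal for non-empty ligand sets; pairs involving an empty set are
#'   recorded as 0.
#' @export
compute_xpi <- function(lib, cutoff = NULL) {
  sets <- ligand_sets(lib, cutoff)
  tids <- names(sets)
  m <- matrix(0, length(tids), length(tids), dimnames = list(tids, tids))
  for (i in seq_along(tids)) {
    for (j in seq.int(i, length(tids))) {
      a <- sets[[i]]; b <- sets[[j]]
      v <- if (length(a) == 0 || length(b) == 0) 0
           else length(intersect(a, b)) / min(length(a), length(b))
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}

#' Propagate seed scores through the cross-pharmacology index (XPI)
#'
#' Each target b receives max over seed targets a of score(a) * XPI(a, b);
#' results below `floor` are dropped.
#'
#' @param seed_scores tibble with `target_id` and `score` (e.g. the best
#'   per-target score across the other methods).
#' @param xpi matrix from [compute_xpi()].
#' @param floor minimum reported score (default 0.2).
#' @return Method-score tibble (`method`, `target_id`, `score`, `evidence`,
#'   evidence naming the best seed target).
#' @export
predict_xpi <- function(seed_scores, xpi, floor = 0.2) {
  seeds <- seed_scores[seed_scores$target_id %in% rownames(xpi), , drop = FALSE]
  if (nrow(seeds) == 0) return(method_score_tibble())
  rows <- purrr::map(colnames(xpi), function(b) {
    contrib <- seeds$score * xpi[seeds$target_id, b]
    k <- which.max(contrib)
    tibble(method = "XPI", target_id = b, score = unname(contrib[k]),
           evidence = as.character(jsonlite::toJSON(list(
             seed = seeds$target_id[k],
             xpi = round(unname(xpi[seeds$target_id[k], b]), 6)),
             auto_unbox = TRUE)))
  })
  out <- bind_rows(rows) %>% filter(.data$score >= floor)
  arrange(out, desc(.data$score), .data$target_id)
}
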