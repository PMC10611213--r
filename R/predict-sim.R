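# SIM: nearest-neighbor descriptor similarity against per-target ligand sets

#' Descriptor-similarity target prediction (SIM)
#'
#' For each target, the score is the maximum similarity between the query and
#' any member of the target's ligand set, under one of the three
#' pharmacophore descriptor channels: PHRAG (multiset Tanimoto), FPD
#' (histogram intersection) or SHED (Gaussian kernel on entropy vectors).
#' Targets scoring below `floor` are omitted.
#'
#' @param query a `molecule` or SMILES string.
#' @param lib a `reference_library` with cached descriptors
#'   ([precompute_descriptors()]).
#' @param descriptor `"PHRAG"`, `"FPD"` or `"SHED"`.
#' @param floor minimum reported score (default 0.3).
#' @param cutoff ligand-set pActivity cutoff (default: library's).
#' @return Tibble `method`, `target_id`, `score`, `evidence` (JSON string
#'   naming the nearest ligand and its similarity), sorted by score
#'   descending then target id.
#' @export
predict_sim <- function(query, lib, descriptor = c("PHRAG", "FPD", "SHED"),
                        floor = 0.3, cutoff = NULL) {
  descriptor <- match.arg(descriptor)
  qd <- query_descriptor(query, lib)
  sets <- ligand_sets(lib, cutoff)
  rows <- purrr::imap(sets, function(ids, tid) {
    if (length(ids) == 0) return(NULL)
    sims <- vapply(ids, function(cid) {
      d <- compound_descriptor(lib, cid)
      switch(descriptor,
        PHRAG = phrag_similarity(qd$phrag, d$phrag),
        FPD = fpd_similarity(qd$fpd, d$fpd),
        SHED = shed_similarity(qd$shed, d$shed))
    }, 1)
    best <- which.max(sims)
    tibble(method = "SIM", target_id = tid, score = unname(sims[best]),
           evidence = jsonlite::toJSON(
             list(descriptor = descriptor, nearest = ids[best],
                  similarity = round(unname(sims[best]), 6)),
             auto_unbox = TRUE) |> as.character())
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(method_score_tibble())
  out %>% filter(.data$score >= floor) %>%
    arrange(desc(.data$score), .data$target_id)
}

method_score_tibble <- function() {
  tibble(method = character(), target_id = character(),
         score = numeric(), evidence = character())
}

query_descriptor <- function(query, lib) {
  if (is.null(lib$descriptors)) {
    stop_offtarget("descriptor cache missing: run precompute_descriptors() first",
                   "offtarget_state_error")
  }
  if (is.character(query)) query <- parse_smiles(query)
  cfg <- lib$descriptors$config
  key <- canonical_smiles(query)
  hit <- lib$descriptors$cache[[key]]
  if (!is.null(hit)) return(hit)
  describe_molecule(query, cfg$max_path_len, cfg$bits, cfg$Dmax, cfg$phrag_len)
}
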