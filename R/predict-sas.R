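# SAS: simplest-active-subgraph signatures
#
# Per target, the signature is the set of small pharmacophore-typed
# subgraphs shared by at least a fraction f of the target's actives, ranked
# smallest-first. Subgraphs are restricted to path-shaped fragments
# (canonical feature-label strings along shortest paths), which makes
# canonicalization and containment checks exact and fast; the restriction is
# documented in the methods vignette.

#' Build per-target active-subgraph signatures
#'
#' @param lib a `reference_library` with cached descriptors.
#' @param f minimum fraction of a target's actives containing a signature
#'   fragment (default 0.8).
#' @param max_atoms maximum fragment size in atoms (default 8).
#' @param max_fragments cap on signature size, smallest fragments first
#'   (default 50).
#' @param cutoff ligand-set pActivity cutoff.
#' @return A `sas_signatures` object: named list target_id -> character
#'   vector of fragment strings, with the parameters recorded; targets with
#'   fewer than 3 actives are skipped with a warning.
#' @export
build_sas_signatures <- function(lib, f = 0.8, max_atoms = 8,
                                 max_fragments = 50, cutoff = NULL) {
  if (f <= 0 || f > 1) stop_offtarget("f must be in (0, 1]", "offtarget_config_error")
  sets <- ligand_sets(lib, cutoff)
  frag_cache <- new.env(parent = emptyenv())
  frags_of <- function(cid) {
    key <- lib$compounds$canonical[match(cid, lib$compounds$compound_id)]
    hit <- frag_cache[[key]]
    if (!is.null(hit)) return(hit)
    mol <- parse_smiles(lib$compounds$smiles[match(cid, lib$compounds$compound_id)])
    fa <- assign_features(mol)
    frag_cache[[key]] <- names(compute_phrag(mol, fa, L = max_atoms))
    frag_cache[[key]]
  }
  skipped <- character(0)
  sig <- purrr::imap(sets, function(ids, tid) {
    if (length(ids) < 3) {
      skipped <<- c(skipped, tid)
      return(NULL)
    }
    per_cpd <- lapply(ids, frags_of)
    tab <- table(unlist(lapply(per_cpd, unique)))
    need <- ceiling(f * length(ids))
    keep <- names(tab)[tab >= need]
    if (length(keep) == 0) return(character(0))
    # smallest-first: by atom count (tokens), then lexicographic
    sizes <- vapply(strsplit(keep, "-", fixed = TRUE), length, 1L)
    keep <- keep[order(sizes, keep)]
    utils::head(keep, max_fragments)
  })
  if (length(skipped) > 0) {
    warn(sprintf("SAS: skipped %d target(s) with < 3 actives: %s",
                 length(skipped), paste(skipped, collapse = ", ")))
  }
  sig <- sig[!vapply(sig, is.null, TRUE)]
  structure(list(signatures = sig, f = f, max_atoms = max_atoms,
                 skipped = skipped),
            class = "sas_signatures")
}

#' @export
print.sas_signatures <- function(x, ...) {
  cat(sprintf("<sas_signatures: %d targets (f=%.2f, <=%d atoms)>\n",
              length(x$signatures), x$f, x$max_atoms))
  invisible(x)
}

#' Score a query against active-subgraph signatures (SAS)
#'
#' Score per target = fraction of that target's signature fragments embedded
#' in the query.
#'
#' @param query a `molecule` or SMILES string.
#' @param signatures a `sas_signatures` from [build_sas_signatures()].
#' @return Method-score tibble (`method`, `target_id`, `score`, `evidence`).
#' @export
predict_sas <- function(query, signatures) {
  if (is.character(query)) query <- parse_smiles(query)
  fa <- assign_features(query)
  qfrags <- names(compute_phrag(query, fa, L = signatures$max_atoms))
  rows <- purrr::imap(signatures$signatures, function(sig, tid) {
    if (length(sig) == 0) return(NULL)
    hit <- sig %in% qfrags
    tibble(method = "SAS", target_id = tid, score = mean(hit),
           evidence = as.character(jsonlite::toJSON(list(
             n_signature = length(sig), n_matched = sum(hit)),
             auto_unbox = TRUE)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(method_score_tibble())
  arrange(out, desc(.data$score), .data$target_id)
}
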