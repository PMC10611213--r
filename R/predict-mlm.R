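# MLM: three-classifier machine-learning consensus
#
# Per target, three binary classifiers - a random forest, a kernel SVM and a
# single-hidden-layer feed-forward network - are trained on identical
# flattened FPD descriptor matrices (positives: the target's ligand set;
# negatives: compounds not annotated to the target, sampled at a fixed
# ratio). The method score is the fraction of positive votes; the consensus
# is positive at a configurable minimum number of votes (default majority,
# 2 of 3).

fpd_feature_vector <- function(fpd) {
  rs <- rowSums(fpd)
  nz <- rs > 0
  m <- unclass(fpd)
  m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  as.numeric(t(m))
}

fpd_feature_matrix <- function(lib, ids) {
  feats <- t(vapply(ids, function(cid) {
    fpd_feature_vector(compound_descriptor(lib, cid)$fpd)
  }, numeric(21 * (lib$descriptors$config$Dmax + 1))))
  rownames(feats) <- ids
  feats
}

#' Train the per-target three-classifier bundles
#'
#' @param lib a `reference_library` with cached descriptors.
#' @param seed RNG seed driving negative sampling and all three learners.
#' @param min_pos minimum positives per target (default 10); targets below
#'   it are skipped and logged.
#' @param neg_ratio negatives sampled per positive (default 3).
#' @param cutoff ligand-set pActivity cutoff.
#' @return An `mlm_bundles` object with per-target classifiers and training
#'   metadata (seed, counts, descriptor version).
#' @export
train_mlm <- function(lib, seed = 1, min_pos = 10, neg_ratio = 3, cutoff = NULL) {
  sets <- ligand_sets(lib, cutoff)
  all_ids <- lib$compounds$compound_id
  skipped <- character(0)
  bundles <- list()
  for (tid in names(sets)) {
    pos <- sets[[tid]]
    if (length(pos) < min_pos) { skipped <- c(skipped, tid); next }
    pool <- setdiff(all_ids, lib$activities$compound_id[
      lib$activities$target_id == tid])
    n_neg <- min(length(pool), neg_ratio * length(pos))
    bundles[[tid]] <- withr::with_seed(seed + hash_string32(tid) %% 10000, {
      neg <- sort(sample(pool, n_neg))
      xs <- fpd_feature_matrix(lib, c(pos, neg))
      y <- factor(c(rep(1, length(pos)), rep(0, length(neg))), levels = c(0, 1))
      # class balance: stratified bootstrap for the forest, class weights for
      # the SVM, case weights for the network; the SVM additionally drops
      # zero-variance columns so feature scaling is well defined
      keep <- which(apply(xs, 2, sd) > 0)
      cw <- ifelse(y == "1", length(neg) / length(pos), 1)
      list(
        rf = randomForest::randomForest(
          xs, y, ntree = 200,
          sampsize = rep(min(length(pos), length(neg)), 2), strata = y),
        svm = e1071::svm(xs[, keep, drop = FALSE], y, kernel = "radial",
                         scale = TRUE,
                         class.weights = c("0" = 1,
                                           "1" = length(neg) / length(pos))),
        svm_keep = keep,
        nnet = nnet::nnet(xs, as.integer(as.character(y)), size = 4,
                          maxit = 300, decay = 1e-3, trace = FALSE,
                          weights = cw),
        meta = list(n_pos = length(pos), n_neg = n_neg, seed = seed,
                    descriptor = "fpd-normalized-1")
      )
    })
  }
  if (length(skipped) > 0) {
    inform(sprintf("MLM: skipped %d target(s) with < %d positives: %s",
                   length(skipped), min_pos, paste(skipped, collapse = ", ")))
  }
  structure(list(bundles = bundles, seed = seed, min_pos = min_pos,
                 neg_ratio = neg_ratio, skipped = skipped),
            class = "mlm_bundles")
}

#' @export
print.mlm_bundles <- function(x, ...) {
  cat(sprintf("<mlm_bundles: %d targets (seed=%d, neg_ratio=%d)>\n",
              length(x$bundles), x$seed, x$neg_ratio))
  invisible(x)
}

#' Score a query with the MLM consensus
#'
#' @param query a `molecule` or SMILES string.
#' @param lib the library the bundles were trained on.
#' @param bundles an `mlm_bundles` object.
#' @param min_votes votes needed for a positive consensus (default 2 of 3;
#'   set 3 for unanimity).
#' @return Method-score tibble with additional column `consensus_positive`.
#' @export
predict_mlm <- function(query, lib, bundles, min_votes = 2) {
  qd <- query_descriptor(query, lib)
  xq <- matrix(fpd_feature_vector(qd$fpd), nrow = 1)
  colnames(xq) <- colnames(fpd_feature_matrix(lib, lib$compounds$compound_id[1]))
  rows <- purrr::imap(bundles$bundles, function(b, tid) {
    # vote from the tree-vote fraction, strict threshold: unlike the class
    # prediction, this breaks 50/50 ties deterministically
    v_rf <- as.integer(predict(b$rf, xq, type = "prob")[1, "1"] > 0.5)
    v_svm <- as.integer(as.character(
      predict(b$svm, xq[, b$svm_keep, drop = FALSE])))
    v_nn <- as.integer(predict(b$nnet, xq)[1, 1] > 0.5)
    votes <- v_rf + v_svm + v_nn
    tibble(method = "MLM", target_id = tid, score = votes / 3,
           consensus_positive = votes >= min_votes,
           evidence = as.character(jsonlite::toJSON(list(
             votes = votes, rf = v_rf, svm = v_svm, ann = v_nn),
             auto_unbox = TRUE)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(mutate(method_score_tibble(), consensus_positive = logical(0)))
  }
  arrange(out, desc(.data$score), .data$target_id)
}
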