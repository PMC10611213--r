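# SAR: per-target regularized QSAR scorers on fingerprint bits
#
# Ridge-penalized logistic models (glmnet) over the hashed path-fingerprint
# bits: one model per target family (target class) as a fallback, and one
# specialized model per target with enough actives. Scores are logistic
# responses in [0, 1].

fp_bit_matrix <- function(lib) {
  cfg <- lib$descriptors$config
  ids <- lib$compounds$compound_id
  rows <- integer(0); cols <- integer(0)
  for (i in seq_along(ids)) {
    bits <- compound_descriptor(lib, ids[i])$fp
    rows <- c(rows, rep(i, length(bits)))
    cols <- c(cols, as.integer(bits) + 1L)
  }
  m <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(length(ids), cfg$bits))
  rownames(m) <- ids
  m
}

fp_bit_vector <- function(fp, bits) {
  v <- Matrix::sparseMatrix(i = rep(1, length(fp)), j = as.integer(fp) + 1L,
                            x = 1, dims = c(1, bits))
  v
}

#' Train SAR models
#'
#' @param lib a `reference_library` with cached descriptors.
#' @param seed RNG seed (recorded; the fit itself is deterministic).
#' @param lambda ridge penalty used for scoring (default 0.01).
#' @param min_pos minimum actives for a per-target model (default 3);
#'   below it, the family model stands in.
#' @param cutoff ligand-set pActivity cutoff.
#' @return A `sar_models` object.
#' @export
train_sar <- function(lib, seed = 1, lambda = 0.01, min_pos = 3, cutoff = NULL) {
  x <- fp_bit_matrix(lib)
  sets <- ligand_sets(lib, cutoff)
  classes <- setNames(lib$targets$target_class, lib$targets$target_id)
  ids <- rownames(x)

  fit_logistic <- function(y) {
    if (length(unique(y)) < 2) return(NULL)
    glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = c(0.1, lambda), standardize = FALSE)
  }

  family_models <- list()
  for (cls in unique(classes)) {
    fam_targets <- names(classes)[classes == cls]
    members <- unique(unlist(sets[fam_targets]))
    y <- as.integer(ids %in% members)
    family_models[[cls]] <- fit_logistic(y)
  }
  target_models <- list()
  small <- character(0)
  for (tid in names(sets)) {
    pos <- sets[[tid]]
    if (length(pos) < min_pos) { small <- c(small, tid); next }
    y <- as.integer(ids %in% pos)
    target_models[[tid]] <- fit_logistic(y)
  }
  if (length(small) > 0) {
    inform(sprintf("SAR: %d target(s) fall back to their family model: %s",
                   length(small), paste(small, collapse = ", ")))
  }
  structure(list(target_models = target_models, family_models = family_models,
                 classes = classes, lambda = lambda, seed = seed,
                 bits = lib$descriptors$config$bits,
                 fallback_targets = small),
            class = "sar_models")
}

#' @export
print.sar_models <- function(x, ...) {
  cat(sprintf("<sar_models: %d target models, %d family models (lambda=%g)>\n",
              length(x$target_models), length(x$family_models), x$lambda))
  invisible(x)
}

#' Score a query with the SAR models
#'
#' @param query a `molecule` or SMILES string.
#' @param lib the library the models were trained on.
#' @param models a `sar_models` object.
#' @return Method-score tibble (`method`, `target_id`, `score`, `evidence`).
#' @export
predict_sar <- function(query, lib, models) {
  qd <- query_descriptor(query, lib)
  newx <- fp_bit_vector(qd$fp, models$bits)
  rows <- purrr::imap(setNames(nm = names(models$classes)), function(., tid) {
    fit <- models$target_models[[tid]]
    used <- "target"
    if (is.null(fit)) {
      fit <- models$family_models[[unname(models$classes[tid])]]
      used <- "family"
    }
    if (is.null(fit)) {
      stop_offtarget(sprintf("no trained SAR model for target %s or its family", tid),
                     "offtarget_state_error")
    }
    p <- as.numeric(predict(fit, newx, s = models$lambda, type = "response"))
    tibble(method = "SAR", target_id = tid, score = p,
           evidence = as.character(jsonlite::toJSON(
             list(model = used), auto_unbox = TRUE)))
  })
  arrange(bind_rows(rows), desc(.data$score), .data$target_id)
}
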