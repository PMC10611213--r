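# Synthetic reference library, expression atlas and query generator
#
# A desk-scale stand-in for a large proprietary compound-target universe.
# Each target owns a scaffold family: a core SMILES template with two
# decoration slots filled from a substituent vocabulary, so chemical
# validity is guaranteed by construction and family membership is the
# planted ground truth. Potencies are log-normal around a per-target mean
# pActivity (default mean 7.0, sd 0.7, populating all affinity bins); a
# stated fraction of compounds is annotated to a second target to plant
# cross-pharmacology. The expression atlas has block-structured
# tissue-specific genes over a noisy background. Everything is byte-
# deterministic under the spec seed.

SCAFFOLD_TEMPLATES <- c(
  "%sc1ccc(%s)cc1",        # para-substituted benzene
  "%sc1ccc(%s)cn1",        # pyridine
  "%sC1CCN(%s)CC1",        # piperidine
  "%sc1ccc(%s)s1",         # thiophene
  "%sC1CCC(%s)CC1",        # cyclohexane
  "%sc1cc(%s)cc(O)c1",     # phenol
  "%sc1ccc2cc(%s)ccc2c1",  # naphthalene
  "%sN1CCN(%s)CC1"         # piperazine
)

# substituents valid both as prefix chains and as parenthesized branches
# (first and last atom each have a free single valence)
SUBSTITUENT_VOCAB <- c(
  "C", "CC", "CCC", "CCCC", "CC(C)C", "CO", "OC", "CCO", "OCC", "CN",
  "NC", "CCN", "F", "Cl", "Br", "CC(=O)N", "CC(=O)O", "CCCO", "CCOC", "CCC(C)O"
)

#' Specification of a synthetic study
#'
#' Defines the generator's conditions: library size and composition, the
#' potency model, the cross-pharmacology overlap, and the expression-atlas
#' layout. Same spec + seed always produces byte-identical outputs.
#'
#' @param seed master seed.
#' @param n_targets number of targets / scaffold families (default 8).
#' @param actives_per_target actives per family (default 20).
#' @param potency_mean,potency_sd pActivity distribution (default 7.0, 0.7).
#' @param overlap_fraction fraction of compounds annotated to a second
#'   target (default 0.1).
#' @param vocab substituent vocabulary.
#' @param tissues tissue labels of the atlas.
#' @param species species tags (first one is the human reference).
#' @param n_background_genes noise-only genes in the atlas (default 24).
#' @param block_size planted tissue-specific block size in genes (default 2).
#' @param planted_mean home-tissue expression of planted genes (default 5.0).
#' @param noise_sd background noise sd (default 0.25).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 17, n_targets = 8, actives_per_target = 20,
                           potency_mean = 7.0, potency_sd = 0.7,
                           overlap_fraction = 0.1,
                           vocab = SUBSTITUENT_VOCAB,
                           tissues = c("brain", "liver", "heart", "kidney",
                                       "lung", "muscle", "intestine", "skin"),
                           species = c("human", "rat"),
                           n_background_genes = 24, block_size = 2,
                           planted_mean = 5.0, noise_sd = 0.25) {
  vocab <- unique(vocab)
  stopifnot(n_targets >= 1, actives_per_target >= 1, block_size >= 1)
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop_offtarget("overlap_fraction must be in [0, 1]", "offtarget_config_error")
  }
  n_combos <- length(vocab)^2
  if (n_combos < 2 * actives_per_target) {
    stop_offtarget("substituent vocabulary too small for requested actives",
                   "offtarget_config_error")
  }
  structure(list(
    seed = seed, n_targets = n_targets,
    actives_per_target = actives_per_target,
    potency_mean = potency_mean, potency_sd = potency_sd,
    overlap_fraction = overlap_fraction, vocab = vocab,
    tissues = tissues, species = species,
    n_background_genes = n_background_genes, block_size = block_size,
    planted_mean = planted_mean, noise_sd = noise_sd
  ), class = "synthetic_spec")
}

combo_smiles <- function(spec, target_index, combo_index) {
  v <- length(spec$vocab)
  tpl <- SCAFFOLD_TEMPLATES[((target_index - 1) %% length(SCAFFOLD_TEMPLATES)) + 1]
  a <- ((combo_index - 1) %/% v) + 1
  b <- ((combo_index - 1) %% v) + 1
  sprintf(tpl, spec$vocab[a], spec$vocab[b])
}

synthetic_target_table <- function(spec) {
  tibble(
    target_id = sprintf("T%02d", seq_len(spec$n_targets)),
    gene_symbol = sprintf("GENE%02d", seq_len(spec$n_targets)),
    target_class = rep(target_classes(),
                       length.out = spec$n_targets),
    species = "human")
}

# combos used by the library, per target (deterministic under spec seed)
library_combos <- function(spec) {
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_targets), function(t) {
      sort(sample(length(spec$vocab)^2, spec$actives_per_target))
    })
  })
}

#' Generate the synthetic reference library
#'
#' @param spec a `synthetic_spec`.
#' @return List: `library` (a `reference_library`) and `ground_truth`
#'   (tibble `compound_id`, `target_id`, `smiles`; overlap compounds carry
#'   two rows).
#' @export
gen_reference_library <- function(spec) {
  targets <- synthetic_target_table(spec)
  combos <- library_combos(spec)
  rows <- withr::with_seed(spec$seed + 1, {
    out <- list()
    cid <- 0
    for (t in seq_len(spec$n_targets)) {
      for (k in seq_len(spec$actives_per_target)) {
        cid <- cid + 1
        compound_id <- sprintf("C%04d", cid)
        smiles <- combo_smiles(spec, t, combos[[t]][k])
        pact <- rnorm(1, spec$potency_mean, spec$potency_sd)
        out[[length(out) + 1]] <- tibble(
          compound_id = compound_id, smiles = smiles,
          target_id = targets$target_id[t],
          target_class = targets$target_class[t],
          activity_type = sample(ACTIVITY_TYPES, 1,
                                 prob = c(0.6, 0.2, 0.1, 0.1)),
          value_nm = 10^(9 - pact),
          moa = sample(c("inhibitor", "antagonist", "agonist"), 1,
                       prob = c(0.5, 0.3, 0.2)),
          source = "synthetic")
      }
    }
    acts <- bind_rows(out)
    # plant cross-pharmacology: a fraction of compounds binds a second target
    n_overlap <- round(spec$overlap_fraction * nrow(acts))
    if (n_overlap > 0 && spec$n_targets > 1) {
      pick <- sort(sample(nrow(acts), n_overlap))
      extra <- acts[pick, , drop = FALSE]
      t_idx <- match(extra$target_id, targets$target_id)
      second <- (t_idx %% spec$n_targets) + 1
      extra$target_id <- targets$target_id[second]
      extra$target_class <- targets$target_class[second]
      extra$value_nm <- 10^(9 - rnorm(n_overlap, spec$potency_mean - 0.5,
                                      spec$potency_sd))
      acts <- bind_rows(acts, extra)
    }
    acts
  })
  lib <- make_reference_library(rows)
  ground_truth <- rows %>%
    distinct(.data$compound_id, .data$target_id, .data$smiles) %>%
    arrange(.data$compound_id, .data$target_id)
  list(library = lib, ground_truth = ground_truth)
}

#' Generate held-out analog query drugs
#'
#' Queries are new decorations of the library's scaffolds - same core, a
#' substituent combination never used by the library - labelled with the
#' scaffold's target.
#'
#' @param spec a `synthetic_spec`.
#' @param library_result result of [gen_reference_library()] for this spec.
#' @param held_out_fraction queries per target as a fraction of
#'   actives_per_target, in (0, 1\] (default 0.25).
#' @return Tibble `compound_id`, `smiles`, `true_target`.
#' @export
gen_query_drugs <- function(spec, library_result, held_out_fraction = 0.25) {
  if (held_out_fraction <= 0 || held_out_fraction > 1) {
    stop_offtarget("held_out_fraction must be in (0, 1]", "offtarget_config_error")
  }
  n_q <- max(1, round(held_out_fraction * spec$actives_per_target))
  combos <- library_combos(spec)
  targets <- synthetic_target_table(spec)
  withr::with_seed(spec$seed + 2, {
    rows <- lapply(seq_len(spec$n_targets), function(t) {
      free <- setdiff(seq_len(length(spec$vocab)^2), combos[[t]])
      pick <- sort(sample(free, min(n_q, length(free))))
      tibble(
        compound_id = sprintf("Q%02d_%02d", t, seq_along(pick)),
        smiles = vapply(pick, function(k) combo_smiles(spec, t, k), ""),
        true_target = targets$target_id[t])
    })
    bind_rows(rows)
  })
}

#' Generate per-species expression atlases with planted blocks
#'
#' Target genes are split into blocks of `block_size`; each block gets a
#' home tissue (cycling through the tissue list) where its genes express at
#' `planted_mean`; everywhere else, and for background genes, values are
#' |N(0.5, noise_sd)| (log2(TPM+1) scale). Non-human species reuse the
#' human pattern with independent noise; ortholog maps are
#' identity-with-suffix.
#'
#' @param spec a `synthetic_spec`.
#' @return List: `atlases` (named list of `expression_atlas`),
#'   `ortholog_map` (tibble `human_symbol`, `species`, `species_symbol`),
#'   `blocks` (tibble `gene`, `block`, `home_tissue`).
#' @export
gen_expression_atlas <- function(spec) {
  targets <- synthetic_target_table(spec)
  genes <- c(targets$gene_symbol,
             sprintf("BG%03d", seq_len(spec$n_background_genes)))
  n_planted <- nrow(targets)
  block_of <- ceiling(seq_len(n_planted) / spec$block_size)
  home <- spec$tissues[((block_of - 1) %% length(spec$tissues)) + 1]
  blocks <- tibble(gene = targets$gene_symbol, block = block_of,
                   home_tissue = home)

  atlases <- list()
  for (si in seq_along(spec$species)) {
    sp <- spec$species[si]
    mat <- withr::with_seed(spec$seed + 10 + si, {
      m <- matrix(abs(rnorm(length(genes) * length(spec$tissues),
                            0.5, spec$noise_sd)),
                  nrow = length(genes),
                  dimnames = list(genes, spec$tissues))
      for (g in seq_len(n_planted)) {
        m[g, home[g]] <- abs(rnorm(1, spec$planted_mean, spec$noise_sd))
      }
      m
    })
    if (sp != spec$species[1]) {
      rownames(mat) <- paste0(genes, "_", sp)
    }
    atlases[[sp]] <- expression_atlas(mat, sp,
                                      provenance = sprintf("synthetic seed=%d", spec$seed))
  }
  ortholog_map <- bind_rows(lapply(spec$species, function(sp) {
    tibble(human_symbol = genes, species = sp,
           species_symbol = if (sp == spec$species[1]) genes
                            else paste0(genes, "_", sp))
  }))
  list(atlases = atlases, ortholog_map = ortholog_map, blocks = blocks)
}

#' Generate a clinical-exposure table for a set of drugs
#'
#' Cmax values are log-normal around 1 uM (sd one log-unit), a realistic
#' free-plasma range for approved oral drugs.
#'
#' @param spec a `synthetic_spec`.
#' @param drugs tibble with `compound_id` (and optionally `true_target`).
#' @return Tibble `drug_id`, `cmax_um`, `intended_targets`, `dose_note`.
#' @export
gen_exposure_table <- function(spec, drugs) {
  withr::with_seed(spec$seed + 3, {
    tibble(
      drug_id = drugs$compound_id,
      cmax_um = signif(10^rnorm(nrow(drugs), 0, 0.5), 4),
      intended_targets = if ("true_target" %in% names(drugs))
        drugs$true_target else NA_character_,
      dose_note = "synthetic steady-state free Cmax")
  })
}

#' Evidence flags for the synthetic targets
#'
#' Every synthetic target carries a literature-evidence flag; tests that
#' need evidence-negative targets subset this table.
#'
#' @param spec a `synthetic_spec`.
#' @return Tibble `target_id`, `disease`, `source`.
#' @export
gen_evidence_table <- function(spec) {
  targets <- synthetic_target_table(spec)
  tibble(target_id = targets$target_id,
         disease = "synthetic-indication",
         source = "synthetic-benchmark")
}

#' Write the complete synthetic fixture set to a directory
#'
#' Emits the exact file formats the pipeline consumes: `library.smi`,
#' `activities.csv`, `atlas_<species>.tsv`, `orthologs.tsv`,
#' `exposure.csv`, `evidence.csv`, `queries.smi` and `ground_truth.tsv`.
#'
#' @param spec a `synthetic_spec`.
#' @param dir output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- gen_reference_library(spec)
  queries <- gen_query_drugs(spec, gen)
  atlas <- gen_expression_atlas(spec)
  exposure <- gen_exposure_table(spec, queries)
  evidence <- gen_evidence_table(spec)

  paths <- c(
    library = file.path(dir, "library.smi"),
    activities = file.path(dir, "activities.csv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    exposure = file.path(dir, "exposure.csv"),
    evidence = file.path(dir, "evidence.csv"),
    queries = file.path(dir, "queries.smi"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    target_genes = file.path(dir, "target_genes.tsv"))

  lib <- gen$library
  writeLines(paste(lib$compounds$smiles, lib$compounds$compound_id, sep = "\t"),
             paths["library"])
  acts <- lib$activities
  attr(acts, "rejected") <- NULL
  readr::write_csv(format_numeric_cols(acts), paths["activities"])
  write_descriptor_table(atlas$ortholog_map, paths["orthologs"])
  readr::write_csv(format_numeric_cols(exposure), paths["exposure"])
  readr::write_csv(evidence, paths["evidence"])
  writeLines(paste(queries$smiles, queries$compound_id, sep = "\t"),
             paths["queries"])
  write_descriptor_table(gen$ground_truth, paths["ground_truth"])
  targets <- synthetic_target_table(spec)
  write_descriptor_table(
    tibble(target_id = targets$target_id, gene = targets$gene_symbol),
    paths["target_genes"])
  for (sp in names(atlas$atlases)) {
    p <- file.path(dir, sprintf("atlas_%s.tsv", sp))
    m <- atlas$atlases[[sp]]$mat
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write_descriptor_table(df, p)
    paths[sprintf("atlas_%s", sp)] <- p
  }
  invisible(paths)
}
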