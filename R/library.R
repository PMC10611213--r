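# The annotated reference compound-target universe
#
# A reference_library bundles the compound, target and activity tables with a
# per-compound descriptor cache keyed by canonical structure. Potencies are
# normalized to pActivity = 9 - log10(value in nM) = -log10(mol/L).

ACTIVITY_COLUMNS <- c("compound_id", "smiles", "target_id", "target_class",
                      "activity_type", "value_nm", "moa", "source")
ACTIVITY_TYPES <- c("IC50", "Ki", "EC50", "Kd")

#' Convert a potency in nM to pActivity
#'
#' \eqn{pActivity = -\log_{10}(\mathrm{mol/L}) = 9 - \log_{10}(\mathrm{nM})}.
#' 100 nM gives 7.0; 1 nM gives 9.0; 1000 nM (1 uM) gives 6.0, the
#' sub-micromolar boundary.
#'
#' @param value_nm positive potency value(s) in nM.
#' @return pActivity value(s).
#' @export
to_pactivity <- function(value_nm) {
  if (any(!is.finite(value_nm) | value_nm <= 0)) {
    stop_offtarget("activity values must be positive and finite",
                   "offtarget_value_error")
  }
  9 - log10(value_nm)
}

#' Convert pActivity back to nM
#' @param pactivity pActivity value(s).
#' @return Potency in nM.
#' @export
from_pactivity <- function(pactivity) 10^(9 - pactivity)

new_reference_library <- function(compounds, targets, activities,
                                  ligand_cutoff = 5.0) {
  lib <- structure(
    list(compounds = compounds, targets = targets, activities = activities,
         ligand_cutoff = ligand_cutoff,
         descriptors = NULL, rejected = attr(activities, "rejected")),
    class = "reference_library"
  )
  issues <- check_library_integrity(lib)
  if (nrow(issues) > 0) {
    stop_offtarget(
      paste0("library integrity violations:\n",
             paste(utils::capture.output(print(issues)), collapse = "\n")),
      "offtarget_integrity_error")
  }
  lib
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf(
    "<reference_library: %d compounds, %d targets, %d activities%s>\n",
    nrow(x$compounds), nrow(x$targets), nrow(x$activities),
    if (!is.null(x$descriptors)) ", descriptors cached" else ""))
  invisible(x)
}

#' Referential-integrity check for a reference library
#'
#' @param lib a `reference_library`.
#' @return Tibble of violations (`table`, `id`, `problem`); zero rows when
#'   the library is consistent.
#' @export
check_library_integrity <- function(lib) {
  issues <- list()
  orphan_c <- setdiff(lib$activities$compound_id, lib$compounds$compound_id)
  if (length(orphan_c) > 0) {
    issues[[length(issues) + 1]] <- tibble(
      table = "activities", id = orphan_c, problem = "unknown compound_id")
  }
  orphan_t <- setdiff(lib$activities$target_id, lib$targets$target_id)
  if (length(orphan_t) > 0) {
    issues[[length(issues) + 1]] <- tibble(
      table = "activities", id = orphan_t, problem = "unknown target_id")
  }
  dup_c <- lib$compounds$compound_id[duplicated(lib$compounds$compound_id)]
  if (length(dup_c) > 0) {
    issues[[length(issues) + 1]] <- tibble(
      table = "compounds", id = unique(dup_c), problem = "duplicate compound_id")
  }
  bad_cls <- setdiff(unique(lib$targets$target_class), target_classes())
  if (length(bad_cls) > 0) {
    issues[[length(issues) + 1]] <- tibble(
      table = "targets", id = bad_cls, problem = "target_class outside vocabulary")
  }
  if (nrow(lib$activities) > 0) {
    bad_p <- abs(lib$activities$pactivity -
                   (9 - log10(lib$activities$value_nm))) > 1e-9
    if (any(bad_p)) {
      issues[[length(issues) + 1]] <- tibble(
        table = "activities", id = lib$activities$compound_id[bad_p],
        problem = "pactivity inconsistent with value_nm")
    }
  }
  if (length(issues) == 0) {
    tibble(table = character(), id = character(), problem = character())
  } else bind_rows(issues)
}

#' Assemble a reference library from in-memory tables
#'
#' Rows with unparsable SMILES are rejected with a line-numbered report;
#' duplicate (compound, target, activity type) rows collapse to the most
#' potent value (lowest nM).
#'
#' @param activities tibble with the documented activity schema columns
#'   (`compound_id`, `smiles`, `target_id`, `target_class`, `activity_type`,
#'   `value_nm`, `moa`, `source`).
#' @param compounds optional tibble (`compound_id`, `smiles`, `name`); when
#'   omitted, compounds are taken from the activity table.
#' @param ligand_cutoff pActivity cutoff used when building per-target ligand
#'   sets (default 5.0, i.e. 10 uM).
#' @return A `reference_library`; the rejection report is in `$rejected`.
#' @export
make_reference_library <- function(activities, compounds = NULL,
                                   ligand_cutoff = 5.0) {
  missing_cols <- setdiff(ACTIVITY_COLUMNS, names(activities))
  if (length(missing_cols) > 0) {
    stop_offtarget(sprintf("activity table is missing column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   "offtarget_schema_error")
  }
  activities <- as_tibble(activities)
  activities$moa[is.na(activities$moa) | activities$moa == ""] <- "unknown"

  # validate structures once per distinct compound
  if (is.null(compounds)) {
    compounds <- distinct(activities, .data$compound_id, .data$smiles)
    compounds$name <- NA_character_
  }
  canon <- rep(NA_character_, nrow(compounds))
  reason <- rep(NA_character_, nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    res <- tryCatch(canonical_smiles(parse_smiles(compounds$smiles[i])),
                    offtarget_error = function(e) e)
    if (inherits(res, "condition")) reason[i] <- conditionMessage(res)
    else canon[i] <- res
  }
  rejected_compounds <- compounds[!is.na(reason), , drop = FALSE]
  rejected_compounds$reason <- reason[!is.na(reason)]
  rejected_compounds$line <- which(!is.na(reason))
  compounds <- compounds[is.na(reason), , drop = FALSE]
  compounds$canonical <- canon[is.na(reason)]

  n_before <- nrow(activities)
  activities <- filter(activities, .data$compound_id %in% compounds$compound_id)
  n_rejected_rows <- n_before - nrow(activities)
  if (n_rejected_rows > 0) {
    inform(sprintf("rejected %d activity row(s) referencing %d unparsable compound(s)",
                   n_rejected_rows, nrow(rejected_compounds)))
  }

  bad_val <- !is.finite(activities$value_nm) | activities$value_nm <= 0
  if (any(bad_val)) {
    inform(sprintf("rejected %d activity row(s) with non-positive values", sum(bad_val)))
    activities <- activities[!bad_val, , drop = FALSE]
  }

  # most-potent collapse for replicate (compound, target, type) measurements
  activities <- activities %>%
    group_by(.data$compound_id, .data$target_id, .data$activity_type) %>%
    arrange(.data$value_nm, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(pactivity = to_pactivity(.data$value_nm)) %>%
    arrange(.data$compound_id, .data$target_id, .data$activity_type)

  targets <- activities %>%
    distinct(.data$target_id, .data$target_class) %>%
    mutate(gene_symbol = .data$target_id, species = "human") %>%
    arrange(.data$target_id)
  dup_t <- targets$target_id[duplicated(targets$target_id)]
  if (length(dup_t) > 0) {
    stop_offtarget(sprintf("target(s) with conflicting class labels: %s",
                           paste(unique(dup_t), collapse = ", ")),
                   "offtarget_schema_error")
  }

  attr(activities, "rejected") <- list(
    compounds = as_tibble(rejected_compounds),
    n_activity_rows = n_rejected_rows + sum(bad_val))
  new_reference_library(arrange(compounds, .data$compound_id),
                        targets, activities, ligand_cutoff)
}

#' Load a reference library from files
#'
#' @param compounds_path SMILES (`.smi`, one per line with optional
#'   tab-separated id) or SDF file of structures, or `NULL` to take
#'   structures from the activity table.
#' @param activities_path CSV with the documented activity schema.
#' @param ligand_cutoff see [make_reference_library()].
#' @return A `reference_library`.
#' @export
load_library <- function(activities_path, compounds_path = NULL,
                         ligand_cutoff = 5.0) {
  if (!file.exists(activities_path)) {
    stop_offtarget(sprintf("file not found: %s", activities_path),
                   "offtarget_io_error")
  }
  activities <- readr::read_csv(activities_path, show_col_types = FALSE,
                                comment = "#")
  compounds <- NULL
  if (!is.null(compounds_path)) {
    compounds <- if (grepl("\\.sdf$", compounds_path, ignore.case = TRUE)) {
      read_sdf_file(compounds_path)
    } else {
      read_smiles_file(compounds_path)
    }
    compounds$name <- NA_character_
  }
  make_reference_library(activities, compounds, ligand_cutoff)
}

#' Ligand set of a target
#'
#' The compounds with pActivity at or above the cutoff against the target,
#' in deterministic (compound id) order. The cutoff boundary is inclusive.
#'
#' @param lib a `reference_library`.
#' @param target_id target identifier.
#' @param cutoff pActivity cutoff; defaults to the library's `ligand_cutoff`.
#' @return Character vector of compound ids.
#' @export
ligand_set <- function(lib, target_id, cutoff = NULL) {
  if (!target_id %in% lib$targets$target_id) {
    stop_offtarget(sprintf("unknown target '%s'", target_id),
                   "offtarget_value_error")
  }
  cutoff <- cutoff %||% lib$ligand_cutoff
  ids <- lib$activities %>%
    filter(.data$target_id == !!target_id, .data$pactivity >= cutoff) %>%
    pull(.data$compound_id)
  sort(unique(ids))
}

#' All ligand sets at once
#' @param lib a `reference_library`.
#' @param cutoff pActivity cutoff; defaults to the library's.
#' @return Named list target_id -> character vector of compound ids.
#' @export
ligand_sets <- function(lib, cutoff = NULL) {
  cutoff <- cutoff %||% lib$ligand_cutoff
  hits <- lib$activities %>%
    filter(.data$pactivity >= cutoff) %>%
    distinct(.data$target_id, .data$compound_id) %>%
    arrange(.data$target_id, .data$compound_id)
  out <- split(hits$compound_id, hits$target_id)
  # targets with no qualifying ligands still appear, as empty sets
  missing <- setdiff(lib$targets$target_id, names(out))
  out[missing] <- list(character(0))
  out[sort(names(out))]
}

#' Precompute and cache per-compound descriptors
#'
#' Computes the fingerprint, feature assignment, FPD, SHED and PHRAG for
#' every library compound, keyed by canonical structure so duplicated
#' structures are computed once.
#'
#' @param lib a `reference_library`.
#' @param max_path_len,bits fingerprint parameters.
#' @param Dmax FPD distance range.
#' @param phrag_len PHRAG maximum fragment length.
#' @return The library with `$descriptors` populated.
#' @export
precompute_descriptors <- function(lib, max_path_len = 7, bits = 2048,
                                   Dmax = 10, phrag_len = 5) {
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(lib$compounds))) {
    key <- lib$compounds$canonical[i]
    if (!is.null(cache[[key]])) next
    cache[[key]] <- describe_molecule(parse_smiles(lib$compounds$smiles[i]),
                                      max_path_len, bits, Dmax, phrag_len)
  }
  lib$descriptors <- list(
    cache = cache,
    config = list(max_path_len = max_path_len, bits = bits, Dmax = Dmax,
                  phrag_len = phrag_len))
  lib
}

describe_molecule <- function(mol, max_path_len = 7, bits = 2048,
                              Dmax = 10, phrag_len = 5) {
  fa <- assign_features(mol)
  list(
    fp = compute_fingerprint(mol, max_path_len, bits),
    features = fa,
    fpd = compute_fpd(mol, fa, Dmax),
    shed = compute_shed(compute_fpd(mol, fa, Dmax)),
    phrag = compute_phrag(mol, fa, phrag_len)
  )
}

compound_descriptor <- function(lib, compound_id) {
  if (is.null(lib$descriptors)) {
    stop_offtarget("descriptor cache missing: run precompute_descriptors() first",
                   "offtarget_state_error")
  }
  key <- lib$compounds$canonical[match(compound_id, lib$compounds$compound_id)]
  lib$descriptors$cache[[key]]
}

#' Persist a reference library as a directory of TSVs plus a JSON manifest
#'
#' @param lib a `reference_library`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_descriptor_table(lib$compounds, file.path(dir, "compounds.tsv"))
  write_descriptor_table(lib$targets, file.path(dir, "targets.tsv"))
  acts <- lib$activities
  attr(acts, "rejected") <- NULL
  write_descriptor_table(acts, file.path(dir, "activities.tsv"))
  manifest <- list(format = "offtarget-library-1",
                   ligand_cutoff = lib$ligand_cutoff,
                   n_compounds = nrow(lib$compounds),
                   n_targets = nrow(lib$targets),
                   n_activities = nrow(lib$activities))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a library persisted with [save_library()]
#' @param dir directory written by [save_library()].
#' @return A `reference_library`.
#' @export
load_library_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$format, "offtarget-library-1")) {
    stop_offtarget("not an offtarget library directory", "offtarget_io_error")
  }
  compounds <- as_tibble(utils::read.delim(file.path(dir, "compounds.tsv"),
                                           stringsAsFactors = FALSE))
  if ("name" %in% names(compounds)) {
    compounds$name <- as.character(compounds$name)
  }
  targets <- as_tibble(utils::read.delim(file.path(dir, "targets.tsv"),
                                         stringsAsFactors = FALSE))
  activities <- as_tibble(utils::read.delim(file.path(dir, "activities.tsv"),
                                            stringsAsFactors = FALSE))
  # pactivity is stored rounded for byte-stable TSVs; restore the exact value
  activities$pactivity <- 9 - log10(activities$value_nm)
  new_reference_library(compounds, targets, activities,
                        manifest$ligand_cutoff)
}
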