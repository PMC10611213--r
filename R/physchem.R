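# Physicochemical profiling
#
# MW from standard atomic masses (implicit hydrogens included), logP and TPSA
# from the atomic-contribution tables shipped in inst/extdata (versions
# logp-1 / tpsa-1), structural counts (HBD, HBA, amides, rotatable bonds)
# from documented graph rules, and an ESOL-style logS estimate.

ATOMIC_MASSES <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Se = 78.971,
  Br = 79.904, I = 126.904
)

load_contrib_tables <- function() {
  if (is.null(the$tpsa_tbl)) {
    path <- system.file("extdata", "tpsa_contributions.tsv", package = "offtarget")
    the$tpsa_tbl <- utils::read.delim(path, comment.char = "#",
                                      na.strings = "", stringsAsFactors = FALSE)
    path2 <- system.file("extdata", "logp_contributions.tsv", package = "offtarget")
    lp <- utils::read.delim(path2, comment.char = "#", stringsAsFactors = FALSE)
    the$logp_tbl <- setNames(lp$value, lp$class)
  }
  invisible(NULL)
}

atom_environment <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  env <- tibble(
    element = mol$atoms$element, aromatic = as.integer(mol$atoms$aromatic),
    charge = mol$atoms$charge, hcount = mol$atoms$hcount,
    n_single = 0L, n_double = 0L, n_triple = 0L, n_aromatic = 0L
  )
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      for (i in c(b$a1[k], b$a2[k])) {
        if (b$aromatic[k]) env$n_aromatic[i] <- env$n_aromatic[i] + 1L
        else if (b$order[k] == 1) env$n_single[i] <- env$n_single[i] + 1L
        else if (b$order[k] == 2) env$n_double[i] <- env$n_double[i] + 1L
        else env$n_triple[i] <- env$n_triple[i] + 1L
      }
    }
  }
  env
}

tpsa_atom <- function(env_row, tbl) {
  for (r in seq_len(nrow(tbl))) {
    row <- tbl[r, ]
    if (row$element != env_row$element) next
    ok <- TRUE
    for (f in c("aromatic", "charge", "hcount", "n_single", "n_double",
                "n_triple", "n_aromatic")) {
      if (!is.na(row[[f]]) && row[[f]] != env_row[[f]]) { ok <- FALSE; break }
    }
    if (ok) return(row$tpsa)
  }
  0
}

logp_class <- function(mol, i, env, amide_n, nitro_n) {
  a <- mol$atoms
  el <- a$element[i]
  adj <- attr(env, "adj")
  nb <- adj$nbrs[[i]]
  if (el == "C") {
    if (a$aromatic[i]) return("C.ar")
    if (env$n_double[i] > 0 && any(a$element[nb] == "O")) return("C.carbonyl")
    if (any(a$element[nb] %in% c("N", "O"))) return("C.het")
    return("C.al")
  }
  if (el == "N") {
    if (a$charge[i] != 0) return("N.charged")
    if (a$aromatic[i]) return("N.ar")
    if (nitro_n[i]) return("N.nitro")
    if (amide_n[i]) return("N.amide")
    if (all(a$element[nb] == "C") && env$n_double[i] + env$n_triple[i] == 0) {
      return("N.amine")
    }
    return("N.other")
  }
  if (el == "O") {
    if (a$charge[i] < 0) return("O.charged")
    if (a$aromatic[i]) return("O.ar")
    if (env$n_double[i] > 0) return("O.carbonyl")
    if (a$hcount[i] > 0) return("O.hydroxyl")
    return("O.ether")
  }
  if (el == "S") return(if (a$aromatic[i]) "S.ar" else "S.al")
  if (el %in% c("P", "F", "Cl", "Br", "I", "B")) return(el)
  "other"
}

structural_groups <- function(mol) {
  a <- mol$atoms
  adj <- adjacency(mol)
  n <- n_atoms(mol)
  has_double_o <- vapply(seq_len(n), function(i) {
    b <- mol$bonds
    if (nrow(b) == 0 || a$element[i] != "C") return(FALSE)
    any((b$a1 == i & b$order == 2 & !b$aromatic & a$element[b$a2] == "O") |
        (b$a2 == i & b$order == 2 & !b$aromatic & a$element[b$a1] == "O"))
  }, TRUE)
  nitro_n <- vapply(seq_len(n), function(i) {
    a$element[i] == "N" && sum(a$element[adj$nbrs[[i]]] == "O") >= 2
  }, TRUE)
  amide_n <- vapply(seq_len(n), function(i) {
    a$element[i] == "N" && any(has_double_o[adj$nbrs[[i]]])
  }, TRUE)
  # amide groups: carbonyl C -- N pairs
  amide_pairs <- 0L
  for (i in which(has_double_o)) {
    amide_pairs <- amide_pairs + sum(a$element[adj$nbrs[[i]]] == "N")
  }
  list(carbonyl_c = has_double_o, nitro_n = nitro_n, amide_n = amide_n,
       n_amide = amide_pairs, adj = adj)
}

rotatable_bond_count <- function(mol, groups) {
  b <- mol$bonds
  if (nrow(b) == 0) return(0L)
  g <- mol_igraph(mol)
  bridge_ids <- igraph::bridges(g)
  deg <- igraph::degree(g)
  cnt <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1 || b$aromatic[k]) next
    if (!(k %in% bridge_ids)) next # ring bond
    i <- b$a1[k]; j <- b$a2[k]
    if (deg[i] < 2 || deg[j] < 2) next # terminal
    amide <- (groups$carbonyl_c[i] && mol$atoms$element[j] == "N") ||
             (groups$carbonyl_c[j] && mol$atoms$element[i] == "N")
    if (amide) next
    cnt <- cnt + 1L
  }
  cnt
}

#' Physicochemical profile of a molecule
#'
#' Molecular weight (standard atomic masses, implicit H included), logP and
#' TPSA from the shipped atomic-contribution tables, an ESOL-style logS
#' estimate, and structural counts: hydrogen-bond donors (N/O bearing H),
#' acceptors (all N + O), amide groups (carbonyl C bonded to N) and rotatable
#' bonds (acyclic single bonds between non-terminal heavy atoms, amide C-N
#' excluded).
#'
#' @param mol a `molecule` (or a SMILES string, parsed on the fly).
#' @return A one-row tibble: `mw`, `logp`, `logs`, `tpsa`, `hbd`, `hba`,
#'   `n_amide`, `n_rotatable`.
#' @examples
#' compute_physchem("CCO")
#' @export
compute_physchem <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  load_contrib_tables()
  a <- mol$atoms
  if (nrow(a) == 0) {
    return(tibble(mw = 0, logp = 0, logs = 0, tpsa = 0, hbd = 0L, hba = 0L,
                  n_amide = 0L, n_rotatable = 0L))
  }
  unknown <- setdiff(a$element, names(ATOMIC_MASSES))
  if (length(unknown) > 0) {
    stop_offtarget(sprintf("no atomic mass for element(s): %s",
                           paste(unknown, collapse = ", ")),
                   "offtarget_chem_error")
  }
  mw <- sum(ATOMIC_MASSES[a$element]) + sum(a$hcount) * ATOMIC_MASSES[["H"]]

  env <- atom_environment(mol)
  groups <- structural_groups(mol)
  attr(env, "adj") <- groups$adj

  tpsa <- sum(vapply(seq_len(nrow(a)), function(i) {
    if (a$element[i] %in% c("N", "O")) tpsa_atom(env[i, ], the$tpsa_tbl) else 0
  }, 1))

  lp_tbl <- the$logp_tbl
  logp <- sum(vapply(seq_len(nrow(a)), function(i) {
    cls <- logp_class(mol, i, env, groups$amide_n, groups$nitro_n)
    contrib <- if (cls %in% names(lp_tbl)) lp_tbl[[cls]] else lp_tbl[["other"]]
    hcls <- if (a$element[i] == "C") "H.C" else "H.het"
    contrib + a$hcount[i] * lp_tbl[[hcls]]
  }, 1))

  hbd <- sum(a$element %in% c("N", "O") & a$hcount > 0)
  hba <- sum(a$element %in% c("N", "O"))
  n_rot <- rotatable_bond_count(mol, groups)
  arom_prop <- mean(a$aromatic)
  logs <- 0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * n_rot - 0.74 * arom_prop

  tibble(mw = mw, logp = logp, logs = logs, tpsa = tpsa,
         hbd = as.integer(hbd), hba = as.integer(hba),
         n_amide = as.integer(groups$n_amide), n_rotatable = as.integer(n_rot))
}

#' Physicochemical profiles for a table of compounds
#'
#' @param compounds tibble with columns `compound_id` and `smiles`.
#' @return Input columns plus the `compute_physchem()` columns, one row per
#'   compound.
#' @export
physchem_table <- function(compounds) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  profiles <- purrr::map(compounds$smiles, compute_physchem)
  bind_cols(compounds[, c("compound_id", "smiles")], bind_rows(profiles))
}

#' Classify a profile under the 3/75 rule
#'
#' The 3/75 heuristic: compounds with logP < 3 and TPSA > 75 A^2 carry lower
#' toxicity risk (`compliant`); logP > 3 with TPSA < 75 marks the high-risk
#' `lipophilic` quadrant; everything else - including boundary values at
#' exactly 3 or exactly 75 - is `intermediate`.
#'
#' @param profile data frame with columns `logp` and `tpsa` (e.g. from
#'   [compute_physchem()]), or a numeric logP when `tpsa` is given.
#' @param tpsa optional numeric TPSA, used when `profile` is numeric.
#' @return Input tibble with a `rule_3_75` factor column (`compliant`,
#'   `lipophilic`, `intermediate`), or the bare factor for numeric input.
#' @export
classify_rule_3_75 <- function(profile, tpsa = NULL) {
  if (is.numeric(profile)) {
    profile <- tibble(logp = profile, tpsa = tpsa)
    bare <- TRUE
  } else bare <- FALSE
  stopifnot(all(c("logp", "tpsa") %in% names(profile)))
  cat3 <- dplyr::case_when(
    profile$logp < 3 & profile$tpsa > 75 ~ "compliant",
    profile$logp > 3 & profile$tpsa < 75 ~ "lipophilic",
    TRUE ~ "intermediate"
  )
  cat3 <- factor(cat3, levels = c("compliant", "lipophilic", "intermediate"))
  if (bare) return(cat3)
  dplyr::mutate(profile, rule_3_75 = cat3)
}

#' Write a descriptor table as TSV
#'
#' Stable column order, one row per molecule, plain TSV (no quoting).
#'
#' @param df data frame of descriptors.
#' @param path output path.
#' @param header_comment optional comment lines (each prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(format_numeric_cols(df), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed-width numeric formatting so that repeated runs are byte-identical
format_numeric_cols <- function(df, digits = 6) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) {
      out <- formatC(col, format = "f", digits = digits)
      out[is.na(col)] <- "NA"
      out
    } else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
}
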