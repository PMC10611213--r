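# Pharmacophore atom typing
#
# The shipped rule table ("ph-1") assigns each atom a (possibly empty) set of
# labels from the six-role vocabulary. Labels are not exclusive: an hydroxyl
# oxygen is both donor and acceptor; a carboxylic oxygen additionally carries
# NEG (pH 7.4 approximation). The assignment is a pure function of the 2D
# graph and the rule-table id.

FEATURE_RULE_TABLES <- c("ph-1")

#' Assign pharmacophore features to every atom
#'
#' Rule table `"ph-1"`:
#' * `DON` — N or O carrying at least one hydrogen.
#' * `ACC` — N or O with an available lone pair; amide nitrogens, nitro
#'   oxygens, positively charged nitrogens and aromatic NH are excluded.
#' * `ARO` — every atom flagged aromatic.
#' * `HYD` — non-aromatic C, S or halogen with no N/O neighbor and no formal
#'   charge.
#' * `POS` — formal charge > 0, or an sp3 amine nitrogen (protonated at
#'   physiological pH): non-aromatic, no multiple bonds, not an amide N.
#' * `NEG` — formal charge < 0, or either oxygen of a carboxylic acid group.
#'
#' @param mol a `molecule`.
#' @param rules rule-table id; only `"ph-1"` is registered.
#' @return A `feature_assignment`: list with `labels` (one character vector
#'   per atom) and `rules` (the rule-table id).
#' @examples
#' fa <- assign_features(parse_smiles("CCO"))
#' fa$labels[[3]] # oxygen: ACC + DON
#' @export
assign_features <- function(mol, rules = "ph-1") {
  if (!rules %in% FEATURE_RULE_TABLES) {
    stop_offtarget(sprintf("unknown feature rule table '%s'", rules),
                   "offtarget_config_error")
  }
  a <- mol$atoms
  n <- nrow(a)
  adj <- adjacency(mol)
  nb_el <- function(i) a$element[adj$nbrs[[i]]]

  # helper predicates over the graph
  has_double_to <- function(i, el) {
    b <- mol$bonds
    if (nrow(b) == 0) return(FALSE)
    hit <- (b$a1 == i & b$order == 2 & !b$aromatic & a$element[b$a2] == el) |
           (b$a2 == i & b$order == 2 & !b$aromatic & a$element[b$a1] == el)
    any(hit)
  }
  n_multiple <- function(i) {
    b <- mol$bonds
    if (nrow(b) == 0) return(0L)
    sum((b$a1 == i | b$a2 == i) & !b$aromatic & b$order >= 2)
  }
  carbonyl_c <- vapply(seq_len(n), function(i) {
    a$element[i] == "C" && has_double_to(i, "O")
  }, TRUE)
  # nitro N: nitrogen with >= 2 oxygen neighbors, at least one via double bond
  # or carrying the charged [N+](=O)[O-] pattern
  nitro_n <- vapply(seq_len(n), function(i) {
    a$element[i] == "N" && sum(nb_el(i) == "O") >= 2 &&
      (has_double_to(i, "O") || a$charge[i] > 0)
  }, TRUE)
  amide_n <- vapply(seq_len(n), function(i) {
    a$element[i] == "N" && any(carbonyl_c[adj$nbrs[[i]]])
  }, TRUE)
  # carboxylic acid: carbonyl carbon that also bears -OH (or O-)
  carboxyl_o <- rep(FALSE, n)
  for (i in which(carbonyl_c)) {
    onb <- adj$nbrs[[i]][a$element[adj$nbrs[[i]]] == "O"]
    acid <- any(a$hcount[onb] > 0 | a$charge[onb] < 0)
    if (acid && length(onb) >= 2) carboxyl_o[onb] <- TRUE
  }

  labels <- vector("list", n)
  for (i in seq_len(n)) {
    el <- a$element[i]
    lab <- character(0)
    if (a$aromatic[i]) lab <- c(lab, "ARO")
    if (el %in% c("N", "O")) {
      if (a$hcount[i] > 0) lab <- c(lab, "DON")
      acc <- TRUE
      if (el == "O" && any(nitro_n[adj$nbrs[[i]]])) acc <- FALSE
      if (el == "N") {
        if (amide_n[i] || nitro_n[i] || a$charge[i] > 0) acc <- FALSE
        if (a$aromatic[i] && a$hcount[i] > 0) acc <- FALSE # pyrrole-type
      }
      if (acc) lab <- c(lab, "ACC")
    }
    if (!a$aromatic[i] && a$charge[i] == 0 &&
        el %in% c("C", "S", "F", "Cl", "Br", "I") &&
        !any(nb_el(i) %in% c("N", "O"))) {
      lab <- c(lab, "HYD")
    }
    if (a$charge[i] > 0) lab <- c(lab, "POS")
    if (el == "N" && !a$aromatic[i] && !amide_n[i] && !nitro_n[i] &&
        a$charge[i] == 0 && n_multiple(i) == 0 &&
        all(nb_el(i) == "C")) {
      lab <- unique(c(lab, "POS")) # basic amine
    }
    if (a$charge[i] < 0) lab <- c(lab, "NEG")
    if (carboxyl_o[i]) lab <- unique(c(lab, "NEG"))
    labels[[i]] <- sort(unique(lab))
  }
  structure(list(labels = labels, rules = rules), class = "feature_assignment")
}

#' @export
print.feature_assignment <- function(x, ...) {
  cat(sprintf("<feature_assignment (%s): %d atoms, %d featured>\n",
              x$rules, length(x$labels),
              sum(vapply(x$labels, length, 1L) > 0)))
  invisible(x)
}

featured_atoms <- function(features) {
  which(vapply(features$labels, length, 1L) > 0)
}

# one token per atom: sorted labels joined with "+", or "x" when unfeatured
atom_feature_token <- function(features, i) {
  lab <- features$labels[[i]]
  if (length(lab) == 0) "x" else paste(lab, collapse = "+")
}
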