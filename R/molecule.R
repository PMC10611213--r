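# 2D molecular graphs from SMILES
#
# The parser covers the SMILES subset needed for drug-like organic molecules:
# the organic subset (B C N O P S F Cl Br I), aromatic lowercase atoms,
# bracket atoms with explicit H counts and formal charges, bonds - = # :,
# branches, ring closures (including %nn) and dot-separated fragments.
# Stereo markers (/ \ @) are accepted and ignored: every descriptor in this
# package is a function of the 2D graph only.

VALENCE_SETS <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

#' Construct a molecule from explicit atom and bond tables
#'
#' Low-level constructor used by the SMILES parser and the SDF reader.
#' Checks the structural invariants: contiguous 1-based atom indices, bonds
#' referencing existing atoms, no self-bonds.
#'
#' @param atoms tibble with columns `element`, `aromatic`, `charge`, `hcount`.
#' @param bonds tibble with columns `a1`, `a2`, `order` (1, 2 or 3) and
#'   `aromatic` (logical). Aromatic bonds carry `order = 1`.
#' @param smiles source text, if any.
#' @param id opaque identifier.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds, smiles = NA_character_, id = NULL) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n)) {
      stop_offtarget("bond references a non-existent atom", "offtarget_chem_error")
    }
    if (any(bonds$a1 == bonds$a2)) {
      stop_offtarget("self-bond is not allowed", "offtarget_chem_error")
    }
  }
  structure(
    list(atoms = atoms, bonds = bonds, smiles = smiles, id = id),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule%s: %d atoms, %d bonds%s>\n",
    if (!is.null(x$id)) paste0(" ", x$id) else "",
    nrow(x$atoms), nrow(x$bonds),
    if (!is.na(x$smiles)) paste0(" | ", x$smiles) else ""
  ))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' An empty molecule
#'
#' Zero atoms, zero bonds. Descriptors of the empty molecule are empty by
#' convention, never an error.
#' @return A `molecule` with no atoms.
#' @export
empty_molecule <- function() {
  molecule(
    tibble(element = character(), aromatic = logical(),
           charge = integer(), hcount = integer()),
    tibble(a1 = integer(), a2 = integer(), order = integer(),
           aromatic = logical())
  )
}

parse_error <- function(text, pos, what) {
  stop_offtarget(
    sprintf("SMILES parse error at position %d in \"%s\": %s", pos, text, what),
    "offtarget_parse_error"
  )
}

implicit_h_for <- function(element, bosum) {
  vals <- VALENCE_SETS[[element]]
  if (is.null(vals)) return(NA_integer_)
  ok <- vals[vals >= bosum]
  if (length(ok) == 0) return(-1L)
  as.integer(min(ok) - bosum)
}

# per-atom bonding environment for the implicit-H model: order sum (aromatic
# bonds count 1), connection count, and presence of a non-aromatic
# double/triple bond
atom_bond_env <- function(n, bonds) {
  bosum <- rep(0, n); nconn <- rep(0L, n); multi <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      o <- if (bonds$aromatic[k]) 1 else bonds$order[k]
      for (i in c(bonds$a1[k], bonds$a2[k])) {
        bosum[i] <- bosum[i] + o
        nconn[i] <- nconn[i] + 1L
        if (!bonds$aromatic[k] && bonds$order[k] >= 2) multi[i] <- TRUE
      }
    }
  }
  list(bosum = bosum, nconn = nconn, multi = multi)
}

# standard implicit-H inference. Aromatic atoms follow the usual lowercase
# conventions: aromatic C carries 3 - connections hydrogens (0 with an
# exocyclic multiple bond); aromatic N/O/S/P carry none unless written with
# an explicit H. Non-aromatic atoms use the smallest sufficient valence.
infer_hcount <- function(element, aromatic, bosum, nconn, multi) {
  if (aromatic) {
    if (element == "C") {
      if (multi) return(max(0L, as.integer(4 - bosum)))
      return(max(0L, as.integer(3 - nconn)))
    }
    return(0L)
  }
  implicit_h_for(element, bosum)
}

#' Parse a SMILES string into a molecular graph
#'
#' @param text a single non-empty SMILES string.
#' @param id optional identifier attached to the molecule.
#' @return A `molecule` with implicit hydrogen counts resolved by the
#'   standard smallest-sufficient-valence rule (N and P may be 3 or 5, S may
#'   be 2, 4 or 6).
#' @examples
#' parse_smiles("CCO")
#' parse_smiles("c1ccccc1")
#' @export
parse_smiles <- function(text, id = NULL) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || nchar(text) == 0) {
    stop_offtarget("SMILES text must be a single non-empty string",
                   "offtarget_parse_error")
  }
  chars <- strsplit(text, "")[[1]]
  n_ch <- length(chars)

  elements <- character(); aromatic <- logical()
  charges <- integer(); hexplicit <- integer() # NA = infer
  bonds <- list()
  prev <- NA_integer_
  pending <- NULL # list(order, aromatic)
  stack <- integer()
  rings <- list() # key = ring id, value = list(atom, pending)
  i <- 1

  add_atom <- function(el, arom, charge, hcount) {
    elements[length(elements) + 1] <<- el
    aromatic[length(aromatic) + 1] <<- arom
    charges[length(charges) + 1] <<- charge
    hexplicit[length(hexplicit) + 1] <<- hcount
    idx <- length(elements)
    if (!is.na(prev)) {
      b <- pending %||% list(order = 1L, aromatic = (aromatic[prev] && arom))
      bonds[[length(bonds) + 1]] <<- c(prev, idx, b$order, as.integer(b$aromatic))
    }
    pending <<- NULL
    prev <<- idx
    idx
  }

  close_ring <- function(key, pos) {
    if (is.na(prev)) parse_error(text, pos, "ring bond before any atom")
    open <- rings[[key]]
    if (is.null(open)) {
      rings[[key]] <<- list(atom = prev, pending = pending)
      pending <<- NULL
    } else {
      b <- pending %||% open$pending %||%
        list(order = 1L, aromatic = (aromatic[open$atom] && aromatic[prev]))
      if (open$atom == prev) parse_error(text, pos, "ring bond to the same atom")
      bonds[[length(bonds) + 1]] <<- c(open$atom, prev, b$order, as.integer(b$aromatic))
      rings[[key]] <<- NULL
      pending <<- NULL
    }
  }

  while (i <= n_ch) {
    ch <- chars[i]
    two <- if (i < n_ch) paste0(ch, chars[i + 1]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE, 0L, NA_integer_); i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L, NA_integer_); i <- i + 1
    } else if (ch %in% AROMATIC_OK) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_); i <- i + 1
    } else if (ch == "[") {
      j <- which(chars[(i + 1):n_ch] == "]")
      if (length(j) == 0) parse_error(text, i, "unclosed bracket atom")
      inner <- substr(text, i + 1, i + j[1] - 1)
      m <- regmatches(inner, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*)?$", inner))[[1]]
      if (length(m) == 0) parse_error(text, i, sprintf("malformed bracket atom [%s]", inner))
      sym <- m[3]
      arom <- substr(sym, 1, 1) %in% letters
      el <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      if (arom && !(tolower(sym) %in% AROMATIC_OK)) {
        parse_error(text, i, sprintf("element %s cannot be aromatic", el))
      }
      hc <- if (m[5] == "") 0L else if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
      chg <- if (m[6] == "") 0L else {
        num <- sub("^[+-]", "", m[6])
        mag <- if (num == "") 1L else as.integer(num)
        if (substr(m[6], 1, 1) == "-") -mag else mag
      }
      add_atom(el, arom, chg, hc)
      i <- i + j[1] + 1
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch,
        "-" = , "/" = , "\\" = list(order = 1L, aromatic = FALSE),
        "=" = list(order = 2L, aromatic = FALSE),
        "#" = list(order = 3L, aromatic = FALSE),
        ":" = list(order = 1L, aromatic = TRUE)
      )
      i <- i + 1
    } else if (ch == "(") {
      if (is.na(prev)) parse_error(text, i, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) parse_error(text, i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, i); i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n_ch || !grepl("^[0-9]{2}$", substr(text, i + 1, i + 2))) {
        parse_error(text, i, "'%' must be followed by two digits")
      }
      close_ring(substr(text, i + 1, i + 2), i); i <- i + 3
    } else if (ch == ".") {
      if (!is.null(pending)) parse_error(text, i, "bond before '.'")
      prev <- NA_integer_; i <- i + 1
    } else {
      parse_error(text, i, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(stack) > 0) parse_error(text, n_ch, "unclosed branch '('")
  if (length(rings) > 0 && any(!vapply(rings, is.null, TRUE))) {
    parse_error(text, n_ch, "unclosed ring bond")
  }
  if (!is.null(pending)) parse_error(text, n_ch, "dangling bond at end of input")
  if (length(elements) == 0) parse_error(text, 1, "no atoms")

  bond_tbl <- if (length(bonds) == 0) {
    tibble(a1 = integer(), a2 = integer(), order = integer(), aromatic = logical())
  } else {
    bm <- do.call(rbind, bonds)
    tibble(a1 = bm[, 1], a2 = bm[, 2], order = as.integer(bm[, 3]),
           aromatic = as.logical(bm[, 4]))
  }

  n <- length(elements)
  env <- atom_bond_env(n, bond_tbl)
  hcount <- hexplicit
  for (k in seq_len(n)) {
    if (is.na(hcount[k])) {
      h <- infer_hcount(elements[k], aromatic[k], env$bosum[k],
                        env$nconn[k], env$multi[k])
      if (is.na(h)) {
        stop_offtarget(sprintf("no valence model for element %s", elements[k]),
                       "offtarget_chem_error")
      }
      if (h < 0) {
        stop_offtarget(
          sprintf("valence violation at atom %d (%s) in \"%s\": bond order sum %g",
                  k, elements[k], text, env$bosum[k]),
          "offtarget_chem_error")
      }
      hcount[k] <- h
    }
  }

  molecule(
    tibble(element = elements, aromatic = aromatic,
           charge = charges, hcount = as.integer(hcount)),
    bond_tbl, smiles = text, id = id
  )
}

mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  }
  g
}

#' Topological distance matrix (bond counts)
#'
#' Shortest path lengths between every pair of atoms, in bonds. Pairs in
#' different fragments get `Inf`.
#'
#' @param mol a `molecule`.
#' @return A symmetric numeric matrix with a zero diagonal.
#' @export
topological_distances <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  d <- igraph::distances(mol_igraph(mol))
  dimnames(d) <- NULL
  d
}

# neighbor lists with bond labels ("a" for aromatic, else the order)
adjacency <- function(mol) {
  n <- n_atoms(mol)
  nbrs <- vector("list", n)
  labs <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      lab <- if (mol$bonds$aromatic[k]) "a" else as.character(mol$bonds$order[k])
      nbrs[[i]] <- c(nbrs[[i]], j); labs[[i]] <- c(labs[[i]], lab)
      nbrs[[j]] <- c(nbrs[[j]], i); labs[[j]] <- c(labs[[j]], lab)
    }
  }
  list(nbrs = nbrs, labs = labs)
}

dense_rank_chr <- function(key) match(key, sort(unique(key)))

refine_ranks <- function(rank, adj, n) {
  repeat {
    key <- vapply(seq_len(n), function(i) {
      nb <- adj$nbrs[[i]]
      env <- if (length(nb) == 0) "" else
        paste(sort(paste0(adj$labs[[i]], ":", sprintf("%06d", rank[nb]))), collapse = ",")
      paste0(sprintf("%06d", rank[i]), "|", env)
    }, character(1))
    newrank <- dense_rank_chr(key)
    if (length(unique(newrank)) == length(unique(rank)) &&
        all(tapply(seq_len(n), rank, function(ix) length(unique(newrank[ix])) == 1))) {
      return(newrank)
    }
    rank <- newrank
  }
}

# Morgan-style canonical ranks: invariant refinement plus deterministic
# tie-breaking. Atoms left tied after maximal refinement are treated as
# automorphic, which holds for the drug-like graphs this package targets.
canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(integer(0))
  adj <- adjacency(mol)
  a <- mol$atoms
  inv0 <- paste(a$element, as.integer(a$aromatic), a$charge, a$hcount,
                vapply(adj$nbrs, length, 1L), sep = "|")
  rank <- dense_rank_chr(inv0)
  rank <- refine_ranks(rank, adj, n)
  while (length(unique(rank)) < n) {
    shared <- as.integer(names(which(table(rank) > 1)))
    r <- min(shared)
    chosen <- which(rank == r)[1]
    key <- rank * 2L - as.integer(seq_len(n) == chosen)
    rank <- match(key, sort(unique(key)))
    rank <- refine_ranks(rank, adj, n)
  }
  rank
}

atom_token <- function(mol, i, env) {
  a <- mol$atoms[i, ]
  el <- a$element
  sym <- if (a$aromatic) tolower(el) else el
  bare <- el %in% ORGANIC_SUBSET && a$charge == 0 &&
    (!a$aromatic || tolower(el) %in% AROMATIC_OK)
  if (bare) {
    inferred <- infer_hcount(el, a$aromatic, env$bosum[i],
                             env$nconn[i], env$multi[i])
    if (!is.na(inferred) && inferred == a$hcount) return(sym)
  }
  paste0("[", sym,
         if (a$hcount == 1) "H" else if (a$hcount > 1) paste0("H", a$hcount) else "",
         if (a$charge > 0) paste0("+", if (a$charge > 1) a$charge else "") else "",
         if (a$charge < 0) paste0("-", if (a$charge < -1) -a$charge else "") else "",
         "]")
}

bond_token <- function(mol, k) {
  b <- mol$bonds[k, ]
  if (b$aromatic) return("")
  if (b$order == 2) return("=")
  if (b$order == 3) return("#")
  # single bond between two aromatic atoms must be written explicitly
  if (mol$atoms$aromatic[b$a1] && mol$atoms$aromatic[b$a2]) return("-")
  ""
}

# serialize with atoms visited in increasing `rank`; one string per fragment,
# fragments sorted, joined with "."
write_smiles_ranked <- function(mol, rank) {
  n <- n_atoms(mol)
  if (n == 0) return("")
  adj <- adjacency(mol)
  bond_id <- matrix(NA_integer_, n, n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      bond_id[mol$bonds$a1[k], mol$bonds$a2[k]] <- k
      bond_id[mol$bonds$a2[k], mol$bonds$a1[k]] <- k
    }
  }
  env <- atom_bond_env(n, mol$bonds)

  visited <- rep(FALSE, n)
  ring_digit <- new.env(parent = emptyenv())
  digit_counter <- 0

  next_digit <- function() {
    digit_counter <<- digit_counter + 1
    if (digit_counter <= 9) as.character(digit_counter)
    else paste0("%", digit_counter)
  }

  # pre-walk to find back edges (deterministic: neighbors in rank order)
  tree_edge <- rep(FALSE, nrow(mol$bonds) + 1L)
  back_edges <- integer(0)
  pre <- function(i, parent_bond) {
    visited[i] <<- TRUE
    nb <- adj$nbrs[[i]][order(rank[adj$nbrs[[i]]])]
    for (j in nb) {
      k <- bond_id[i, j]
      if (k == parent_bond && tree_edge[k]) next
      if (!visited[j]) {
        tree_edge[k] <<- TRUE
        pre(j, k)
      } else if (!tree_edge[k] && !(k %in% back_edges)) {
        back_edges <<- c(back_edges, k)
      }
    }
  }

  emit <- function(i) {
    visited[i] <<- TRUE
    out <- atom_token(mol, i, env)
    # ring closures at this atom
    my_rings <- back_edges[vapply(back_edges, function(k) {
      mol$bonds$a1[k] == i || mol$bonds$a2[k] == i
    }, TRUE)]
    for (k in my_rings) {
      key <- as.character(k)
      if (is.null(ring_digit[[key]])) {
        d <- next_digit()
        ring_digit[[key]] <- d
        out <- paste0(out, bond_token(mol, k), d)
      } else {
        out <- paste0(out, ring_digit[[key]])
      }
    }
    children <- Filter(function(j) {
      k <- bond_id[i, j]
      tree_edge[k] && !visited[j]
    }, adj$nbrs[[i]][order(rank[adj$nbrs[[i]]])])
    nc <- length(children)
    for (ci in seq_along(children)) {
      j <- children[ci]
      piece <- paste0(bond_token(mol, bond_id[i, j]), emit(j))
      out <- paste0(out, if (ci < nc) paste0("(", piece, ")") else piece)
    }
    out
  }

  roots <- integer(0)
  ord <- order(rank)
  for (i in ord) if (!visited[i]) { roots <- c(roots, i); pre(i, 0L) }
  visited[] <- FALSE
  frags <- vapply(roots, emit, character(1))
  paste(sort(frags), collapse = ".")
}

#' Canonical SMILES serialization
#'
#' Deterministic serialization built on Morgan-style invariant refinement.
#' The canonical form is idempotent: parsing the canonical string and
#' re-canonicalizing yields the same string. Used as the structure key for
#' deduplication and descriptor caching.
#'
#' @param mol a `molecule`.
#' @return A single SMILES string ("" for the empty molecule).
#' @export
canonical_smiles <- function(mol) {
  write_smiles_ranked(mol, canonical_ranks(mol))
}

#' Rewrite a molecule as a randomized (but equivalent) SMILES string
#'
#' Serializes the same graph with a random atom priority, producing an
#' alternative valid SMILES. Used to exercise atom-reindexing invariance of
#' descriptors. Consumes random numbers from the session RNG.
#'
#' @param mol a `molecule`.
#' @return A SMILES string parsing to the same structure.
#' @export
rewrite_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return("")
  write_smiles_ranked(mol, sample(n))
}

#' Read a SMILES file
#'
#' One molecule per line; an optional second tab-separated column supplies
#' the compound id. Lines that fail to parse are reported, never silently
#' dropped.
#'
#' @param path file path.
#' @return A tibble with columns `compound_id`, `smiles`; parse failures are
#'   attached as attribute `rejected` (tibble with `line`, `smiles`, `reason`).
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) {
    stop_offtarget(sprintf("file not found: %s", path), "offtarget_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t")
  smiles <- vapply(parts, `[[`, "", 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][[2]] else sprintf("M%04d", i)
  }, "")
  ok <- logical(length(smiles)); reason <- character(length(smiles))
  for (i in seq_along(smiles)) {
    res <- tryCatch({ parse_smiles(smiles[i]); TRUE },
                    offtarget_error = function(e) conditionMessage(e))
    if (isTRUE(res)) ok[i] <- TRUE else reason[i] <- res
  }
  out <- tibble(compound_id = ids[ok], smiles = smiles[ok])
  attr(out, "rejected") <- tibble(
    line = which(!ok), smiles = smiles[!ok], reason = reason[!ok])
  out
}

#' Read an SDF (V2000) structure file
#'
#' Parsing is delegated to ChemmineR; records are converted to `molecule`
#' graphs (bond order 4 is taken as aromatic, and atoms on aromatic bonds are
#' flagged aromatic).
#'
#' @param path SDF file path.
#' @return A tibble with columns `compound_id`, `smiles` (canonical form of
#'   the converted graph).
#' @export
read_sdf_file <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop_offtarget("ChemmineR is required to read SDF files", "offtarget_io_error")
  }
  sdfs <- ChemmineR::read.SDFset(path)
  rows <- purrr::map(seq_along(sdfs), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_[0-9]+$", "", rownames(ab))
    nb <- if (is.null(dim(bb))) 0 else nrow(bb)
    a1 <- a2 <- ord <- integer(nb); arom <- logical(nb)
    if (nb > 0) {
      a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
      raw <- as.integer(bb[, 3])
      arom <- raw == 4L
      ord <- ifelse(arom, 1L, raw)
    }
    aflag <- rep(FALSE, length(el))
    if (nb > 0) { aflag[a1[arom]] <- TRUE; aflag[a2[arom]] <- TRUE }
    bonds <- tibble(a1 = a1, a2 = a2, order = ord, aromatic = arom)
    env <- atom_bond_env(length(el), bonds)
    hc <- vapply(seq_along(el), function(k) {
      h <- infer_hcount(el[k], aflag[k], env$bosum[k], env$nconn[k],
                        env$multi[k])
      if (is.na(h) || h < 0) 0L else h
    }, 1L)
    mol <- molecule(
      tibble(element = el, aromatic = aflag, charge = 0L, hcount = hc),
      bonds, id = ChemmineR::sdfid(sdf)
    )
    tibble(compound_id = ChemmineR::sdfid(sdf), smiles = canonical_smiles(mol))
  })
  bind_rows(rows)
}
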