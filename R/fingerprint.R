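# Hashed linear-path bit fingerprints
#
# The fingerprint is the set of hash bits of all simple linear paths of
# 1..max_path_len atoms, labelled by element + aromaticity and bond order.
# Construction is versioned ("paths-ph31-1"): the path string is read in the
# lexicographically smaller of its two directions, then hashed with the
# package's fixed 32-bit polynomial hash, modulo the bit-space size.

#' Compute a hashed linear-path fingerprint
#'
#' @param mol a `molecule`.
#' @param max_path_len maximum path length in atoms (default 7).
#' @param bits bit-space size, a power of two (default 2048).
#' @return A `bit_fp`: sorted integer vector of on-bit indices (0-based),
#'   with attributes `bits` and `generator`.
#' @export
compute_fingerprint <- function(mol, max_path_len = 7, bits = 2048) {
  if (max_path_len < 1) {
    stop_offtarget("max_path_len must be >= 1", "offtarget_config_error")
  }
  if (bits < 2 || bitwAnd(bits, bits - 1L) != 0) {
    stop_offtarget("bits must be a power of two", "offtarget_config_error")
  }
  paths <- enumerate_paths(mol, max_path_len)
  on <- sort(unique(vapply(paths, function(s) hash_string32(s) %% bits, 1)))
  structure(as.integer(on), bits = as.integer(bits),
            generator = sprintf("paths-ph31-1/L%d", max_path_len),
            class = "bit_fp")
}

#' @export
print.bit_fp <- function(x, ...) {
  cat(sprintf("<bit_fp: %d bits on / %d (%s)>\n",
              length(x), attr(x, "bits"), attr(x, "generator")))
  invisible(x)
}

# all distinct labelled simple paths with 1..L atoms, canonical direction
enumerate_paths <- function(mol, L) {
  n <- n_atoms(mol)
  if (n == 0) return(character(0))
  adj <- adjacency(mol)
  a <- mol$atoms
  atom_lab <- paste0(a$element, ifelse(a$aromatic, "ar", ""))
  out <- new.env(parent = emptyenv())

  walk <- function(path, labs) {
    i <- path[length(path)]
    fwd <- paste(labs, collapse = "")
    rev_s <- paste(rev(labs), collapse = "")
    key <- if (fwd <= rev_s) fwd else rev_s
    out[[key]] <- TRUE
    if (length(path) >= L) return()
    nb <- adj$nbrs[[i]]
    for (t in seq_along(nb)) {
      j <- nb[t]
      if (j %in% path) next
      walk(c(path, j), c(labs, adj$labs[[i]][t], atom_lab[j]))
    }
  }
  for (i in seq_len(n)) walk(i, atom_lab[i])
  ls(out)
}

#' Tanimoto similarity between two bit fingerprints
#'
#' \eqn{Tc = |A \cap B| / |A \cup B|}. Two empty fingerprints return 0 with a
#' warning: featureless fragments must not look like perfect matches.
#'
#' @param a,b `bit_fp` objects over the same bit-space size.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  ba <- attr(a, "bits") %||% NA_integer_
  bb <- attr(b, "bits") %||% NA_integer_
  if (!is.na(ba) && !is.na(bb) && ba != bb) {
    stop_offtarget("fingerprints have different bit-space sizes",
                   "offtarget_config_error")
  }
  if (length(a) == 0 && length(b) == 0) {
    warn("Tanimoto of two empty fingerprints returned as 0")
    return(0)
  }
  ni <- length(intersect(a, b))
  nu <- length(a) + length(b) - ni
  ni / nu
}

# Tc between one fingerprint and a list of fingerprints (no warnings; used in
# the inner similarity loops)
tanimoto_many <- function(fp, fps) {
  vapply(fps, function(g) {
    if (length(fp) == 0 && length(g) == 0) return(0)
    ni <- length(intersect(fp, g))
    ni / (length(fp) + length(g) - ni)
  }, 1)
}
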