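# Pharmacophore descriptors over the typed 2D graph
#
# FPD: counts of featured-atom pairs by feature pair (21 unordered pairs over
# the six labels) and topological distance bin (1..Dmax plus one overflow
# bin). SHED: the natural-log Shannon entropy of each pair's normalized
# distance histogram. PHRAG: the multiset of feature-label strings read along
# shortest paths between featured atoms.

#' Feature-pair distance distribution (FPD)
#'
#' Every unordered pair of distinct featured atoms contributes one count per
#' label combination to the `[feature pair, distance bin]` matrix. Distances
#' above `Dmax` fall in the overflow bin; unreachable pairs (different
#' fragments) are skipped.
#'
#' @param mol a `molecule`.
#' @param features a `feature_assignment` for `mol`.
#' @param Dmax largest resolved topological distance (default 10).
#' @param normalize if `TRUE`, each pair's row is scaled to sum to 1 (all-zero
#'   rows stay zero).
#' @return An `fpd_matrix`: 21 x (Dmax + 1) numeric matrix with attributes
#'   `Dmax` and `normalized`.
#' @export
compute_fpd <- function(mol, features, Dmax = 10, normalize = FALSE) {
  if (Dmax < 2) stop_offtarget("Dmax must be >= 2", "offtarget_config_error")
  pairs <- feature_pairs()
  m <- matrix(0, nrow = length(pairs), ncol = Dmax + 1,
              dimnames = list(pairs, c(as.character(seq_len(Dmax)), "gt")))
  fa <- featured_atoms(features)
  if (length(fa) >= 2) {
    d <- topological_distances(mol)
    for (ii in seq_along(fa)[-length(fa)]) {
      for (jj in seq.int(ii + 1, length(fa))) {
        i <- fa[ii]; j <- fa[jj]
        dij <- d[i, j]
        if (!is.finite(dij) || dij < 1) next
        bin <- if (dij <= Dmax) dij else Dmax + 1
        for (la in features$labels[[i]]) {
          for (lb in features$labels[[j]]) {
            m[pair_key(la, lb), bin] <- m[pair_key(la, lb), bin] + 1
          }
        }
      }
    }
  }
  if (normalize) {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  structure(m, Dmax = as.integer(Dmax), normalized = normalize,
            class = c("fpd_matrix", class(m)))
}

#' Shannon entropy descriptors (SHED)
#'
#' One natural-log entropy per feature pair, computed from that pair's
#' normalized distance histogram: \eqn{H = -\sum_i p_i \ln p_i}. A pair with
#' all mass in one bin (or no mass) has H = 0; H is bounded by
#' \eqn{\ln(Dmax + 1)}.
#'
#' @param fpd an `fpd_matrix`.
#' @return A named numeric vector of 21 entropies, class `shed_vector`.
#' @export
compute_shed <- function(fpd) {
  h <- apply(fpd, 1, function(row) {
    s <- sum(row)
    if (s == 0) return(0)
    p <- row[row > 0] / s
    -sum(p * log(p))
  })
  structure(h, class = "shed_vector")
}

#' Pharmacophoric fragment profile (PHRAG)
#'
#' For every pair of featured atoms joined by a shortest path of 2..L atoms,
#' the fragment string is the ordered per-atom feature tokens along one
#' deterministic shortest path (BFS with lowest-index tie-break), read in the
#' lexicographically smaller direction. Unfeatured interior atoms contribute
#' the placeholder token `x`.
#'
#' @param mol a `molecule`.
#' @param features a `feature_assignment` for `mol`.
#' @param L maximum fragment length in atoms (default 5).
#' @return A `phrag_profile`: named integer vector (fragment string ->
#'   multiplicity).
#' @export
compute_phrag <- function(mol, features, L = 5) {
  if (L < 2) stop_offtarget("L must be >= 2", "offtarget_config_error")
  fa <- featured_atoms(features)
  counts <- new.env(parent = emptyenv())
  if (length(fa) >= 2) {
    adj <- adjacency(mol)
    n <- n_atoms(mol)
    for (ii in seq_along(fa)[-length(fa)]) {
      src <- fa[ii]
      # BFS with deterministic predecessors (lowest index wins)
      pred <- rep(NA_integer_, n); dist <- rep(Inf, n)
      dist[src] <- 0; queue <- src
      while (length(queue) > 0) {
        u <- queue[1]; queue <- queue[-1]
        for (v in sort(adj$nbrs[[u]])) {
          if (dist[v] > dist[u] + 1) {
            dist[v] <- dist[u] + 1; pred[v] <- u
            queue <- c(queue, v)
          }
        }
      }
      for (jj in seq.int(ii + 1, length(fa))) {
        dst <- fa[jj]
        if (!is.finite(dist[dst]) || dist[dst] < 1 || dist[dst] > L - 1) next
        path <- dst
        while (path[1] != src) path <- c(pred[path[1]], path)
        toks <- vapply(path, function(k) atom_feature_token(features, k), "")
        fwd <- paste(toks, collapse = "-")
        rev_s <- paste(rev(toks), collapse = "-")
        key <- if (fwd <= rev_s) fwd else rev_s
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  structure(setNames(vapply(keys, function(k) counts[[k]], 1L), keys),
            class = "phrag_profile")
}

#' Multiset Tanimoto similarity between two PHRAG profiles
#'
#' \eqn{\sum_s \min(a_s, b_s) / \sum_s \max(a_s, b_s)} over the union of
#' fragment strings. Two empty profiles return 0.
#'
#' @param a,b `phrag_profile` objects.
#' @return Similarity in \[0, 1\].
#' @export
phrag_similarity <- function(a, b) {
  keys <- union(names(a), names(b))
  if (length(keys) == 0) return(0)
  av <- setNames(rep(0, length(keys)), keys); av[names(a)] <- a
  bv <- setNames(rep(0, length(keys)), keys); bv[names(b)] <- b
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Histogram-intersection similarity between two FPD matrices
#'
#' Generalized Jaccard over the flattened count matrices:
#' \eqn{\sum \min / \sum \max}; 1 iff identical non-empty matrices, 0 when
#' both are empty.
#'
#' @param a,b `fpd_matrix` objects with identical dimensions.
#' @return Similarity in \[0, 1\].
#' @export
fpd_similarity <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    stop_offtarget("FPD matrices have different shapes", "offtarget_config_error")
  }
  den <- sum(pmax(a, b))
  if (den == 0) return(0)
  sum(pmin(a, b)) / den
}

#' Gaussian-kernel similarity between two SHED vectors
#'
#' \eqn{\exp(-\lVert a - b\rVert / s_0)} with a fixed scale `s0`.
#'
#' @param a,b `shed_vector` objects.
#' @param s0 distance scale (default 2).
#' @return Similarity in (0, 1\].
#' @export
shed_similarity <- function(a, b, s0 = 2) {
  exp(-sqrt(sum((as.numeric(a) - as.numeric(b))^2)) / s0)
}
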