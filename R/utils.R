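# shared constants and small numeric helpers

#' Pharmacophore feature vocabulary
#'
#' The six abstract atom roles used by all pharmacophore descriptors:
#' hydrogen-bond acceptor (`ACC`), aromatic (`ARO`), hydrogen-bond donor
#' (`DON`), hydrophobic (`HYD`), negatively ionizable (`NEG`) and positively
#' ionizable (`POS`).
#'
#' @return Character vector of the six feature labels, alphabetical.
#' @export
feature_vocabulary <- function() c("ACC", "ARO", "DON", "HYD", "NEG", "POS")

#' Closed vocabulary of therapeutic target classes
#'
#' @return Character vector of the nine recognized target-class labels.
#' @export
target_classes <- function() {
  c("GPCR", "Enzyme", "Kinase", "NuclearReceptor", "IonChannel",
    "Cytochrome", "Transporter", "OtherFamilies", "Unclassified")
}

# the 21 unordered feature pairs (6 labels, self-pairs included), "ACC:ACC" ...
feature_pairs <- function() {
  v <- feature_vocabulary()
  idx <- which(upper.tri(matrix(0, 6, 6), diag = TRUE), arr.ind = TRUE)
  sort(paste(v[idx[, "row"]], v[idx[, "col"]], sep = ":"))
}

pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = ":"), paste(b, a, sep = ":"))
}

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; exposure tables in the field round
#' half away from zero, and that convention is needed to reproduce printed
#' pCmax values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# 32-bit modular arithmetic on doubles (exact: all intermediates < 2^53)
mulmod32 <- function(a, b) {
  a0 <- a %% 65536
  a1 <- a %/% 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
}

# fixed, versioned polynomial string hash ("ph31-1"); memoized across calls
hash_string32 <- function(s) {
  memo <- the$hash_memo
  if (is.null(memo)) {
    memo <- new.env(parent = emptyenv())
    the$hash_memo <- memo
  }
  h <- memo[[s]]
  if (!is.null(h)) return(h)
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (mulmod32(h, 31) + b) %% 4294967296
  memo[[s]] <- h
  h
}

stop_offtarget <- function(msg, class, ...) {
  abort(msg, class = c(class, "offtarget_error"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
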