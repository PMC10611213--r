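# SEA: set-wise ligand similarity with an extreme-value statistic
#
# The raw score RS between two compound sets is the sum of pairwise Tanimoto
# similarities at or above the threshold tau. Against a random-set background
# with fitted mean mu(n) and spread sigma(n) (n = product of set sizes), the
# z-score is converted to a p-value with the extreme-value form
#   p = 1 - exp(-exp(-(z * pi / sqrt(6) + gamma)))
# gamma the Euler-Mascheroni constant, so z = 0 maps to p ~ 0.4296.

EULER_GAMMA <- 0.57721566490153286

#' Raw SEA score between two fingerprint sets
#'
#' @param fps_a,fps_b lists of `bit_fp` fingerprints.
#' @param tau Tanimoto threshold; pairs below it contribute nothing.
#' @return Sum of qualifying pairwise Tanimoto values (>= 0).
#' @export
sea_raw_score <- function(fps_a, fps_b, tau) {
  rs <- 0
  for (fa in fps_a) {
    tc <- tanimoto_many(fa, fps_b)
    rs <- rs + sum(tc[tc >= tau])
  }
  rs
}

#' Extreme-value p-value for a SEA z-score
#' @param z standardized raw score.
#' @return p in \[0, 1\], strictly decreasing in z.
#' @export
sea_pvalue <- function(z) {
  1 - exp(-exp(-(z * pi / sqrt(6) + EULER_GAMMA)))
}

#' Fit the SEA random-set background
#'
#' Draws random compound-set pairs from the library, computes their raw
#' scores, and fits mu(n) and sigma(n) as functions of the set-size product
#' n. mu is fitted on the individual draws; sigma on the per-grid-point
#' standard deviations.
#'
#' @param lib a `reference_library` with cached descriptors.
#' @param tau Tanimoto threshold (default 0.57).
#' @param set_sizes set sizes making up the sampling grid (pairs are all
#'   size combinations).
#' @param reps draws per grid point (>= 30).
#' @param seed RNG seed; the fit is reproducible given (library, tau, seed).
#' @param mu_form,sigma_form `"linear"` (a + b n) or `"power"` (a n^b).
#' @return A `sea_background` with fitted coefficient lists and diagnostics.
#' @export
fit_sea_background <- function(lib, tau = 0.57, set_sizes = c(2, 4, 8, 16),
                               reps = 40, seed = 1,
                               mu_form = c("linear", "power"),
                               sigma_form = c("power", "linear")) {
  mu_form <- match.arg(mu_form)
  sigma_form <- match.arg(sigma_form)
  if (reps < 30) stop_offtarget("reps must be >= 30", "offtarget_config_error")
  if (length(set_sizes) < 2) {
    stop_offtarget("degenerate size grid", "offtarget_config_error")
  }
  ids <- lib$compounds$compound_id
  if (length(ids) < 2 * max(set_sizes)) {
    stop_offtarget("library too small for the requested set sizes",
                   "offtarget_config_error")
  }
  fps <- lapply(ids, function(cid) compound_descriptor(lib, cid)$fp)
  names(fps) <- ids

  grid <- expand.grid(s1 = set_sizes, s2 = set_sizes)
  grid <- grid[grid$s1 <= grid$s2, , drop = FALSE]
  draws <- withr::with_seed(seed, {
    purrr::pmap(grid, function(s1, s2) {
      rs <- vapply(seq_len(reps), function(r) {
        a <- sample(ids, s1)
        b <- sample(ids, s2)
        sea_raw_score(fps[a], fps[b], tau)
      }, 1)
      tibble(n = s1 * s2, rs = rs)
    }) %>% bind_rows()
  })

  fit_one <- function(x, y, form) {
    if (form == "linear") {
      fit <- lm(y ~ x)
      list(form = "linear", a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
           r2 = summary(fit)$r.squared)
    } else {
      keep <- y > 0
      if (sum(keep) < 2) {
        # all-zero background (tau unreachable): constant floor
        return(list(form = "power", a = 0, b = 0, r2 = NA_real_))
      }
      fit <- lm(log(y[keep]) ~ log(x[keep]))
      list(form = "power", a = exp(unname(coef(fit)[1])), b = unname(coef(fit)[2]),
           r2 = summary(fit)$r.squared)
    }
  }
  mu_fit <- fit_one(draws$n, draws$rs, mu_form)
  per_n <- draws %>% group_by(.data$n) %>%
    summarise(s = sd(.data$rs), .groups = "drop")
  sigma_fit <- fit_one(per_n$n, per_n$s, sigma_form)

  structure(
    list(tau = tau, mu = mu_fit, sigma = sigma_fit, seed = seed,
         set_sizes = set_sizes, reps = reps, draws = draws,
         fp_generator = attr(fps[[1]], "generator")),
    class = "sea_background")
}

#' @export
print.sea_background <- function(x, ...) {
  cat(sprintf(
    "<sea_background: tau=%.2f, mu %s (R2=%.3f), sigma %s, %d draws>\n",
    x$tau, x$mu$form, x$mu$r2, x$sigma$form, nrow(x$draws)))
  invisible(x)
}

eval_fit <- function(fit, n) {
  if (fit$form == "linear") fit$a + fit$b * n else fit$a * n^fit$b
}

sea_mu <- function(bg, n) eval_fit(bg$mu, n)

sea_sigma <- function(bg, n) {
  s <- eval_fit(bg$sigma, n)
  if (any(!is.finite(s) | s <= 0)) {
    stop_offtarget("fitted sigma(n) is non-positive; refit the background",
                   "offtarget_state_error")
  }
  s
}

#' Score one set pair against the background
#'
#' @param rs raw score.
#' @param n set-size product.
#' @param background a `sea_background`.
#' @return Tibble `rs`, `n`, `z`, `p`.
#' @export
sea_score_pair <- function(rs, n, background) {
  z <- (rs - sea_mu(background, n)) / sea_sigma(background, n)
  tibble(rs = rs, n = n, z = z, p = sea_pvalue(z))
}

#' SEA target prediction for a query molecule
#'
#' The query forms a singleton set compared against every target's ligand
#' set; results are sorted by p ascending. The method score reported for the
#' consensus is 1 - p.
#'
#' @param query a `molecule` or SMILES string.
#' @param lib a `reference_library` with cached descriptors.
#' @param background a `sea_background` fitted on this library.
#' @param tau Tanimoto threshold; defaults to the background's tau (a
#'   mismatch is an error).
#' @param cutoff ligand-set pActivity cutoff.
#' @return Tibble `target_id`, `rs`, `n`, `z`, `p`, `score`, `evidence`.
#' @export
predict_sea <- function(query, lib, background, tau = NULL, cutoff = NULL) {
  if (!inherits(background, "sea_background")) {
    stop_offtarget("background must be a sea_background (fit_sea_background)",
                   "offtarget_state_error")
  }
  tau <- tau %||% background$tau
  if (abs(tau - background$tau) > 1e-12) {
    stop_offtarget("tau differs from the background fit; refit the background",
                   "offtarget_config_error")
  }
  qd <- query_descriptor(query, lib)
  sets <- ligand_sets(lib, cutoff)
  rows <- purrr::imap(sets, function(ids, tid) {
    if (length(ids) == 0) return(NULL)
    fps <- lapply(ids, function(cid) compound_descriptor(lib, cid)$fp)
    tc <- tanimoto_many(qd$fp, fps)
    hit <- tc >= tau
    rs <- sum(tc[hit])
    sc <- sea_score_pair(rs, length(ids), background)
    tibble(target_id = tid, rs = rs, n = length(ids), z = sc$z, p = sc$p,
           score = 1 - sc$p,
           evidence = as.character(jsonlite::toJSON(list(
             n_pairs_above_tau = sum(hit), z = round(sc$z, 4),
             p = signif(sc$p, 6)), auto_unbox = TRUE)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(target_id = character(), rs = numeric(), n = integer(),
                  z = numeric(), p = numeric(), score = numeric(),
                  evidence = character()))
  }
  arrange(out, .data$p, .data$target_id)
}
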