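# broom-style tidiers for fitted objects

#' Tidy a SEA background fit
#'
#' @param x a `sea_background`.
#' @param ... unused.
#' @return Tibble with one row per fitted component (`mu`, `sigma`):
#'   `component`, `form`, `a`, `b`, `r_squared`.
#' @export
tidy.sea_background <- function(x, ...) {
  bind_rows(
    tibble(component = "mu", form = x$mu$form, a = x$mu$a, b = x$mu$b,
           r_squared = x$mu$r2),
    tibble(component = "sigma", form = x$sigma$form, a = x$sigma$a,
           b = x$sigma$b, r_squared = x$sigma$r2))
}

#' One-row summary of a SEA background fit
#' @param x a `sea_background`.
#' @param ... unused.
#' @return Tibble: `tau`, `n_draws`, `mu_r_squared`, `seed`.
#' @export
glance.sea_background <- function(x, ...) {
  tibble(tau = x$tau, n_draws = nrow(x$draws), mu_r_squared = x$mu$r2,
         seed = x$seed)
}

#' Tidy the MLM classifier bundles
#' @param x an `mlm_bundles`.
#' @param ... unused.
#' @return One row per trained target: `target_id`, `n_pos`, `n_neg`, `seed`.
#' @export
tidy.mlm_bundles <- function(x, ...) {
  purrr::imap(x$bundles, function(b, tid) {
    tibble(target_id = tid, n_pos = b$meta$n_pos, n_neg = b$meta$n_neg,
           seed = b$meta$seed)
  }) %>% bind_rows()
}

#' One-row summary of the MLM bundles
#' @param x an `mlm_bundles`.
#' @param ... unused.
#' @return Tibble: `n_targets`, `n_skipped`, `neg_ratio`, `seed`.
#' @export
glance.mlm_bundles <- function(x, ...) {
  tibble(n_targets = length(x$bundles), n_skipped = length(x$skipped),
         neg_ratio = x$neg_ratio, seed = x$seed)
}

#' Tidy the SAS signatures
#' @param x a `sas_signatures`.
#' @param ... unused.
#' @return One row per target: `target_id`, `n_fragments`.
#' @export
tidy.sas_signatures <- function(x, ...) {
  tibble(target_id = names(x$signatures),
         n_fragments = vapply(x$signatures, length, 1L))
}
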