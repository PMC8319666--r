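#' Tidy a fitted HMM
#'
#' One row per parameter: initial probabilities, transition probabilities and
#' emission means/sds, in broom's term/estimate layout.
#'
#' @param x A `quiescr_hmm`.
#' @param ... Unused.
#' @return Tibble: `term`, `state`, `to`, `estimate`.
#' @export
tidy.quiescr_hmm <- function(x, ...) {
  st <- factor(x$states, levels = STATES)
  dplyr::bind_rows(
    tibble(term = "pi", state = st, to = factor(NA, levels = STATES),
           estimate = x$pi),
    tidyr::expand_grid(i = 1:3, j = 1:3) |>
      dplyr::mutate(term = "transition",
                    state = st[.data$i], to = st[.data$j],
                    estimate = x$A[cbind(.data$i, .data$j)]) |>
      dplyr::select("term", "state", "to", "estimate"),
    tibble(term = "mu_log", state = st, to = factor(NA, levels = STATES),
           estimate = x$mu),
    tibble(term = "sd_log", state = st, to = factor(NA, levels = STATES),
           estimate = x$sigma)
  )
}

#' Glance at a fitted HMM
#'
#' @param x A `quiescr_hmm`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `n_obs`, `n_seq`, `n_iter`, `converged`.
#' @export
glance.quiescr_hmm <- function(x, ...) {
  tibble(logLik = x$logLik, n_obs = x$n_obs, n_seq = x$n_seq,
         n_iter = x$n_iter, converged = x$converged)
}

#' Augment speeds with decoded states
#'
#' Equivalent to [decode_states()]: returns the per-frame labels and
#' posteriors implied by the model.
#'
#' @param x A `quiescr_hmm`.
#' @param data Speed tibble or numeric speed vector.
#' @param ... Unused.
#' @return A `quiescr_states` tibble.
#' @export
augment.quiescr_hmm <- function(x, data, ...) {
  decode_states(x, data)
}

#' Tidy a screen table
#'
#' Long format: one row per gene x metric, with the classification columns
#' repeated, convenient for faceted plotting.
#'
#' @param x A `quiescr_screen`.
#' @param ... Unused.
#' @return Tibble: `gene`, `metric`, `normalized`, `classification`,
#'   `significant_q`.
#' @export
tidy.quiescr_screen <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::starts_with("norm_"), names_to = "metric",
                        names_prefix = "norm_", values_to = "normalized") |>
    dplyr::select("gene", "metric", "normalized", "classification",
                  "significant_q")
}

#' Glance at a screen table
#'
#' @param x A `quiescr_screen`.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `alpha`, `family_size`,
#'   `alpha_corrected`, `alpha_display`, `n_reduced`, `n_enhanced`,
#'   `n_significant`.
#' @export
glance.quiescr_screen <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    alpha = attr(x, "alpha"),
    family_size = attr(x, "family_size"),
    alpha_corrected = attr(x, "alpha_corrected"),
    alpha_display = attr(x, "alpha_display"),
    n_reduced = sum(x$classification == "reduced"),
    n_enhanced = sum(x$classification == "enhanced"),
    n_significant = sum(x$significant_q, na.rm = TRUE)
  )
}
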