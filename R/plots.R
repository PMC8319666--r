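state_fill_scale <- function() {
  ggplot2::scale_fill_manual(
    values = c(Q = "#2166ac", D = "#fddbc7", R = "#b2182b"),
    drop = FALSE, name = "state"
  )
}

#' Plot a centroid track
#'
#' Path through the arena, colored by true state when present.
#'
#' @param track Track tibble.
#' @return A ggplot.
#' @export
plot_track <- function(track) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$x_px, y = .data$y_px))
  if ("true_state" %in% names(track)) {
    p <- p + ggplot2::geom_path(ggplot2::aes(color = .data$true_state),
                                linewidth = 0.3) +
      ggplot2::scale_color_manual(
        values = c(Q = "#2166ac", D = "#f4a582", R = "#b2182b"),
        drop = FALSE, name = "state")
  } else {
    p <- p + ggplot2::geom_path(linewidth = 0.3)
  }
  p + ggplot2::scale_y_reverse() + # image convention: origin top-left
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Ethogram of decoded states
#'
#' One horizontal band per animal, colored by per-frame state.
#'
#' @param decoded A [decode_states()] tibble.
#' @return A ggplot.
#' @export
plot_states <- function(decoded) {
  ggplot2::ggplot(decoded,
                  ggplot2::aes(x = .data$time_s, y = .data$animal_id,
                               fill = .data$label)) +
    ggplot2::geom_tile() +
    state_fill_scale() +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Emission model of a fitted HMM
#'
#' Per-state Gaussian log-speed densities, weighted by the stationary
#' occupancy of the fitted transition matrix.
#'
#' @param object A `quiescr_hmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quiescr_hmm <- function(object, ...) {
  occ <- stationary_distribution(object$A)
  grid <- purrr::map_dfr(1:3, function(k) {
    y <- seq(object$mu[k] - 4 * object$sigma[k],
             object$mu[k] + 4 * object$sigma[k], length.out = 200)
    tibble(state = factor(object$states[k], levels = STATES),
           log_speed = y,
           density = occ[k] * dnorm(y, object$mu[k], object$sigma[k]))
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$log_speed, y = .data$density,
                                     color = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(
      values = c(Q = "#2166ac", D = "#f4a582", R = "#b2182b"), name = "state") +
    ggplot2::labs(x = "log(speed + epsilon) (log px/s)",
                  y = "occupancy-weighted density") +
    ggplot2::theme_minimal()
}

#' Screen overview bar chart
#'
#' Normalized quiescence per gene, colored by classification, with the
#' neutral-band (or asymmetric-cutoff) boundaries drawn as dashed lines.
#'
#' @param object A `quiescr_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quiescr_screen <- function(object, ...) {
  rule <- attr(object, "rule") %||% "ratio_band"
  cuts <- if (rule == "ratio_band") c(0.8, 1.2) else c(0.6, 1.7)
  df <- as_tibble(object)
  df$gene <- factor(df$gene, levels = df$gene)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$norm_pct_Q,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cuts, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_hline(yintercept = 1, color = "grey20") +
    ggplot2::scale_fill_manual(values = c(reduced = "#b2182b",
                                          neutral = "grey70",
                                          enhanced = "#2166ac",
                                          unresolved = "grey30"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = "normalized % quiescence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  }
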