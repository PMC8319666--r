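#' Default control-regime transition rates
#'
#' Per-second transition rates (row = from, column = to, diagonal zero) of the
#' three-state chain for an untreated, well-fed control animal. Dwelling and
#' quiescence exchange at equal rates; rates into roaming are extremely small,
#' so roaming is rare, matching control behavior in the satiety-quiescence
#' assay.
#'
#' @return A 3x3 numeric matrix with dimnames `from`/`to` over `Q`, `D`, `R`.
#' @export
#' @examples
#' default_control_rates()
default_control_rates <- function() {
  r <- matrix(0, 3, 3, dimnames = list(from = STATES, to = STATES))
  r["Q", "D"] <- 0.02
  r["Q", "R"] <- 0.0002
  r["D", "Q"] <- 0.02
  r["D", "R"] <- 0.001
  r["R", "D"] <- 0.05
  r["R", "Q"] <- 0.005
  r
}

# Log-displacement moments of a 2-D isotropic Gaussian jitter of per-axis sd j:
# the displacement magnitude is Rayleigh(j), so E[log r] = log j + (log 2 - g)/2
# (g = Euler-Mascheroni) and SD[log r] = pi / sqrt(24).
RAYLEIGH_LOG_SHIFT <- (log(2) - 0.57721566490153286) / 2
RAYLEIGH_LOG_SD <- pi / sqrt(24)

#' Default per-state log-speed emission table
#'
#' Quiescence parameters are the log-moments of a Rayleigh displacement with
#' scale `jitter_px`; dwelling is centered at 1 px/s and roaming at 8 px/s.
#'
#' @param jitter_px Quiescent centroid jitter sd (px, per axis).
#' @return Tibble: `state`, `mu_log`, `sd_log`.
#' @export
default_emissions <- function(jitter_px) {
  tibble(
    state = factor(STATES, levels = STATES),
    mu_log = c(log(jitter_px) + RAYLEIGH_LOG_SHIFT, log(1), log(8)),
    sd_log = c(RAYLEIGH_LOG_SD, 0.35, 0.35)
  )
}

#' Simulation configuration for synthetic worm sessions
#'
#' Bundles every constant needed to generate a synthetic single-worm session:
#' the assay timing (1 frame/s for 30 min by default), the per-second
#' transition-rate matrix of the three-state chain, the per-state log-speed
#' emission model, the quiescent centroid-jitter floor, and the arena used for
#' track kinematics and frame rendering.
#'
#' The default quiescence emission parameters are derived from `jitter_px`:
#' quiescent displacement is Rayleigh-distributed with scale `jitter_px`, whose
#' log has mean `log(jitter_px) + (log 2 - gamma)/2` and sd `pi/sqrt(24)`, so
#' the kinematic jitter model and the emission table agree.
#'
#' @param frame_rate_hz Frames per second (default 1).
#' @param duration_s Session length in seconds (default 1800, i.e. 30 min).
#' @param rates 3x3 per-second transition-rate matrix (from x to, diagonal
#'   ignored); see [default_control_rates()].
#' @param emissions Tibble with columns `state`, `mu_log`, `sd_log` giving the
#'   per-state log-speed model in log(px/s). Default derived from `jitter_px`
#'   for `Q` plus dwelling at 1 px/s and roaming at 8 px/s.
#' @param jitter_px Per-axis sd (px) of quiescent centroid jitter.
#' @param turn_sd_rad Angular-diffusion sd (rad/frame) of the roaming heading.
#' @param arena_px Named integer vector `c(width=, height=)` of the arena.
#' @param worm_radius_px Radius (px) of the rendered worm blob.
#'
#' @return A list of class `quiescr_config`.
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 60)
#' cfg$rates
sim_config <- function(frame_rate_hz = 1,
                       duration_s = 1800,
                       rates = default_control_rates(),
                       emissions = NULL,
                       jitter_px = 0.05,
                       turn_sd_rad = 0.2,
                       arena_px = c(width = 256, height = 256),
                       worm_radius_px = 4) {
  if (is.null(emissions)) emissions <- default_emissions(jitter_px)
  cfg <- structure(
    list(
      frame_rate_hz = frame_rate_hz,
      duration_s = duration_s,
      rates = rates,
      emissions = emissions,
      jitter_px = jitter_px,
      turn_sd_rad = turn_sd_rad,
      arena_px = arena_px,
      worm_radius_px = worm_radius_px
    ),
    class = "quiescr_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0) {
    stop("frame_rate_hz must be positive", call. = FALSE)
  }
  n <- cfg$duration_s * cfg$frame_rate_hz
  if (n <= 0 || abs(n - round(n)) > 1e-8) {
    stop("duration_s * frame_rate_hz must be a positive integer frame count",
         call. = FALSE)
  }
  r <- cfg$rates
  if (!is.matrix(r) || !identical(dim(r), c(3L, 3L))) {
    stop("rates must be a 3x3 matrix", call. = FALSE)
  }
  off <- r; diag(off) <- 0
  if (any(off < 0)) stop("transition rates must be non-negative", call. = FALSE)
  row_p <- rowSums(off) / cfg$frame_rate_hz
  bad <- which(row_p > 1 + 1e-12) # exactly 1 is a valid (deterministic) row
  if (length(bad) > 0) {
    stop("per-frame exit probability > 1 for state ",
         paste(STATES[bad], collapse = ", "),
         " (reduce rates or raise frame_rate_hz)", call. = FALSE)
  }
  em <- cfg$emissions
  stopifnot(all(c("state", "mu_log", "sd_log") %in% names(em)), nrow(em) == 3)
  mu <- em$mu_log[match(STATES, as.character(em$state))]
  if (any(is.na(mu)) || !(mu[1] < mu[2] && mu[2] < mu[3])) {
    stop("emission means must satisfy mu_Q < mu_D < mu_R", call. = FALSE)
  }
  if (any(em$sd_log <= 0)) stop("emission sds must be positive", call. = FALSE)
  if (cfg$jitter_px < 0) stop("jitter_px must be >= 0", call. = FALSE)
  if (cfg$worm_radius_px >= min(cfg$arena_px)) {
    stop("worm_radius_px must be smaller than the arena", call. = FALSE)
  }
  invisible(cfg)
}

#' Per-frame transition matrix of a configuration
#'
#' Converts per-second rates to per-frame probabilities linearly:
#' `p[i,j] = r[i,j] / frame_rate_hz` off the diagonal, with the diagonal
#' absorbing the remainder. At 1 frame/s and rates of order 1e-2 and below the
#' linear conversion agrees with the matrix exponential to well under the
#' estimation error, and it makes [transition_rates()] the exact inverse of
#' the generator.
#'
#' @param config A [sim_config()].
#' @return 3x3 per-frame stochastic matrix.
#' @export
per_frame_matrix <- function(config) {
  validate_sim_config(config)
  p <- config$rates / config$frame_rate_hz
  diag(p) <- 0
  diag(p) <- 1 - rowSums(p)
  p
}

#' Stationary distribution of a stochastic matrix
#'
#' Solves `pi P = pi`, `sum(pi) = 1`. If the chain has no unique stationary
#' distribution (e.g. all rates zero, `P = I`), the uniform distribution is
#' returned.
#'
#' @param P A row-stochastic square matrix.
#' @return Named numeric vector summing to 1.
#' @export
#' @examples
#' stationary_distribution(per_frame_matrix(sim_config()))
stationary_distribution <- function(P) {
  K <- nrow(P)
  A <- rbind(t(P) - diag(K), rep(1, K))
  b <- c(rep(0, K), 1)
  pi_hat <- tryCatch(qr.solve(A, b), error = function(e) rep(1 / K, K))
  if (any(!is.finite(pi_hat)) || any(pi_hat < -1e-9)) pi_hat <- rep(1 / K, K)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- rownames(P) %||% STATES[seq_len(K)]
  pi_hat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.quiescr_config <- function(x, ...) {
  n <- x$duration_s * x$frame_rate_hz
  cat("<quiescr_config>\n")
  cat(sprintf("  %g frames/s x %g s = %d frames\n", x$frame_rate_hz,
              x$duration_s, as.integer(round(n))))
  cat("  per-second rates (from -> to):\n")
  print(x$rates)
  cat("  emissions (log px/s):\n")
  print(as.data.frame(x$emissions), row.names = FALSE)
  cat(sprintf("  jitter %g px, arena %d x %d px, worm radius %g px\n",
              x$jitter_px, x$arena_px[["width"]], x$arena_px[["height"]],
              x$worm_radius_px))
  invisible(x)
}
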