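#' Simulate a ground-truth behavioral state sequence
#'
#' Draws a discrete-time Markov chain over quiescence/dwelling/roaming with
#' per-frame transition probabilities `r[i,j] / frame_rate_hz` (see
#' [per_frame_matrix()]). The initial state is drawn from the chain's
#' stationary distribution, so short sessions carry no burn-in artifact.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed; identical `(config, seed)` give identical
#'   sequences.
#' @return Factor of length `duration_s * frame_rate_hz` with levels
#'   `Q`, `D`, `R`.
#' @export
#' @examples
#' s <- simulate_states(sim_config(duration_s = 120), seed = 1)
#' table(s)
simulate_states <- function(config, seed = NULL) {
  validate_sim_config(config)
  P <- per_frame_matrix(config)
  pi0 <- stationary_distribution(P)
  n <- as.integer(round(config$duration_s * config$frame_rate_hz))
  if (!is.null(seed)) set.seed(seed)
  codes <- cpp_sim_markov(n, P, pi0)
  factor(STATES[codes], levels = STATES)
}

emission_vectors <- function(config) {
  em <- config$emissions
  idx <- match(STATES, as.character(em$state))
  list(mu = em$mu_log[idx], sd = em$sd_log[idx])
}

#' Simulate log-normal speed observations for a state sequence
#'
#' Draws one speed per frame from the configured per-state log-speed model
#' (`speed = exp(Normal(mu_s, sd_s))`). This is the pure emission model of the
#' hidden Markov analysis, useful for validating fitting and decoding without
#' track kinematics in between.
#'
#' @param states Factor/character state sequence (levels `Q`, `D`, `R`).
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return Tibble with columns `frame`, `time_s`, `speed_px_s`, `true_state`.
#' @export
simulate_speeds <- function(states, config, seed = NULL) {
  validate_sim_config(config)
  s <- as_state_int(states)
  if (length(s) == 0) stop("states must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ev <- emission_vectors(config)
  sp <- exp(stats::rnorm(length(s), mean = ev$mu[s], sd = ev$sd[s]))
  tibble(
    frame = seq_along(s) - 1L,
    time_s = (seq_along(s) - 1L) / config$frame_rate_hz,
    speed_px_s = sp,
    true_state = as_state_factor(states)
  )
}

#' Simulate a centroid track from a state sequence
#'
#' Kinematics per frame, governed by the true state of the frame being entered:
#' roaming keeps a persistent heading with Gaussian angular diffusion and a
#' log-normal speed; dwelling reverses its heading with probability 1/2 each
#' frame at a low log-normal speed (back-and-forth local movement); quiescence
#' displaces only by isotropic Gaussian centroid jitter of sd `jitter_px`.
#' Positions reflect at the arena boundary. The track starts at the arena
#' center.
#'
#' @inheritParams simulate_speeds
#' @return Tibble of class `TrackSeries` layout: `frame`, `time_s`, `x_px`,
#'   `y_px`, `valid`, `true_state`.
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 60)
#' trk <- simulate_track(simulate_states(cfg, 1), cfg, seed = 2)
simulate_track <- function(states, config, seed = NULL) {
  validate_sim_config(config)
  s <- as_state_int(states)
  if (length(s) == 0) stop("states must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ev <- emission_vectors(config)
  w <- config$arena_px[["width"]]
  h <- config$arena_px[["height"]]
  pos <- cpp_sim_track(s, ev$mu, ev$sd, config$jitter_px, config$turn_sd_rad,
                       config$frame_rate_hz, w, h,
                       (w - 1) / 2, (h - 1) / 2)
  tibble(
    frame = seq_along(s) - 1L,
    time_s = (seq_along(s) - 1L) / config$frame_rate_hz,
    x_px = pos[, 1],
    y_px = pos[, 2],
    valid = TRUE,
    true_state = as_state_factor(states)
  )
}

#' Render a track as a synthetic image stack
#'
#' One grayscale frame per track row: a filled bright disk of radius
#' `config$worm_radius_px` centered at the true centroid on a dark background,
#' plus optional additive Gaussian pixel noise. Coordinates follow the package
#' convention x = column, y = row, 0-based, origin top-left; pixel centers at
#' integers. A radius of 0 lights the single nearest pixel.
#'
#' @param track Track tibble with `x_px`, `y_px` (e.g. from
#'   [simulate_track()]).
#' @param config A [sim_config()]; supplies arena size and worm radius.
#' @param noise_sd Additive Gaussian noise sd (image intensity units, image is
#'   0/1 before noise). Clipped to \[0, 1\].
#' @param seed RNG seed for the noise.
#' @return List of `height x width` numeric matrices in \[0, 1\].
#' @export
render_frames <- function(track, config, noise_sd = 0, seed = NULL) {
  validate_sim_config(config)
  w <- config$arena_px[["width"]]
  h <- config$arena_px[["height"]]
  r <- config$worm_radius_px
  if (r >= min(w, h)) stop("worm radius must be smaller than the arena", call. = FALSE)
  if (any(track$x_px < 0 | track$x_px > w - 1 | track$y_px < 0 | track$y_px > h - 1,
          na.rm = TRUE)) {
    stop("track positions fall outside the arena", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nrow(track)), function(i) {
    img <- matrix(0, nrow = h, ncol = w)
    x <- track$x_px[i]; y <- track$y_px[i]
    if (r <= 0) {
      img[round(y) + 1, round(x) + 1] <- 1
    } else {
      cols <- max(0, floor(x - r)):min(w - 1, ceiling(x + r))
      rows <- max(0, floor(y - r)):min(h - 1, ceiling(y + r))
      d2 <- outer((rows - y)^2, (cols - x)^2, `+`)
      img[rows + 1, cols + 1][d2 <= r^2] <- 1
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    img
  })
}

#' Describe a knockdown effect for a mock screen
#'
#' An effect is a multiplicative perturbation of the control transition-rate
#' matrix, mimicking an RNAi knockdown that changes the animal's tendency to
#' switch states. Identity multipliers reproduce the control regime exactly.
#'
#' @param gene_label Free-text gene label.
#' @param rate_multipliers 3x3 matrix of positive factors applied elementwise
#'   to the control rates (diagonal ignored). Default all 1 (null effect).
#' @param n_treated,n_control Group sizes; defaults 16 treated vs 8 concurrent
#'   controls, within the assay's typical ranges.
#' @return A list of class `quiescr_effect`.
#' @export
#' @examples
#' m <- matrix(1, 3, 3); m[1, 2] <- 2; m[2, 1] <- 0.5 # Q->D up, D->Q down
#' effect_spec("flp-x", m)
effect_spec <- function(gene_label, rate_multipliers = matrix(1, 3, 3),
                        n_treated = 16, n_control = 8) {
  stopifnot(is.matrix(rate_multipliers),
            identical(dim(rate_multipliers), c(3L, 3L)))
  off <- rate_multipliers; diag(off) <- 1
  if (any(off <= 0)) stop("rate multipliers must be positive", call. = FALSE)
  if (n_treated < 1 || n_control < 1) stop("group sizes must be >= 1", call. = FALSE)
  structure(
    list(gene_label = as.character(gene_label),
         rate_multipliers = rate_multipliers,
         n_treated = as.integer(n_treated),
         n_control = as.integer(n_control)),
    class = "quiescr_effect"
  )
}

apply_effect <- function(config, effect) {
  cfg <- config
  m <- effect$rate_multipliers
  diag(m) <- 1
  cfg$rates <- config$rates * m
  tryCatch(validate_sim_config(cfg),
           error = function(e) {
             stop("effect '", effect$gene_label, "': ", conditionMessage(e),
                  call. = FALSE)
           })
  cfg
}

#' Generate a complete mock RNAi screen
#'
#' For each effect, simulates an independent concurrent control group under the
#' control configuration and a treated group under the control rates multiplied
#' by the effect's factors. Per-animal seeds are derived deterministically from
#' the master seed, so the whole screen is reproducible.
#'
#' @param config Control-regime [sim_config()].
#' @param effects List of [effect_spec()] objects (at least one).
#' @param seed Master integer seed.
#' @param level `"states"` to store ground-truth state sequences only (fast,
#'   sufficient for metric/screen validation) or `"tracks"` to store full
#'   centroid tracks.
#' @return List of class `quiescr_screen_sim` with elements `manifest` (one
#'   row per gene: `gene`, `n_control`, `n_treated`, `multipliers` list-column),
#'   `animals` (one row per animal: `gene`, `role`, `animal_id`, `seed`, and a
#'   `data` list-column holding the state factor or track tibble), and
#'   `config`.
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 120)
#' scr <- simulate_screen(cfg, list(effect_spec("null-1")), seed = 1)
#' scr$manifest
simulate_screen <- function(config, effects, seed = 1,
                            level = c("states", "tracks")) {
  validate_sim_config(config)
  level <- match.arg(level)
  if (inherits(effects, "quiescr_effect")) effects <- list(effects)
  if (length(effects) < 1) stop("at least one effect is required", call. = FALSE)
  manifest <- purrr::map_dfr(effects, function(e) {
    tibble(gene = e$gene_label, n_control = e$n_control,
           n_treated = e$n_treated, multipliers = list(e$rate_multipliers))
  })
  counter <- 0
  seed_base <- (as.numeric(seed) * 7919 + 104729) %% 2147483629
  next_seed <- function() {
    # deterministic per-animal stream; stays within 32-bit integer range
    counter <<- counter + 1
    as.integer((seed_base + counter * 65537) %% 2147483629)
  }
  animals <- purrr::map_dfr(effects, function(e) {
    treated_cfg <- apply_effect(config, e)
    grp <- function(role, n, cfg) {
      seeds <- vapply(seq_len(n), function(i) next_seed(), integer(1))
      dat <- lapply(seeds, function(s) {
        states <- simulate_states(cfg, seed = s)
        if (level == "states") states else
          simulate_track(states, cfg, seed = s + 1L)
      })
      tibble(gene = e$gene_label, role = role,
             animal_id = sprintf("%s_%s_%02d", e$gene_label, role, seq_len(n)),
             seed = seeds, data = dat)
    }
    dplyr::bind_rows(grp("control", e$n_control, config),
                     grp("treated", e$n_treated, treated_cfg))
  })
  structure(list(manifest = manifest, animals = animals, config = config,
                 level = level, seed = seed),
            class = "quiescr_screen_sim")
}

#' @export
print.quiescr_screen_sim <- function(x, ...) {
  cat("<quiescr_screen_sim> ", nrow(x$manifest), " gene(s), ",
      nrow(x$animals), " animals (level = ", x$level, ")\n", sep = "")
  print(x$manifest)
  invisible(x)
}
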