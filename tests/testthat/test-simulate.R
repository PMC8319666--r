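test_that("state simulation is reproducible and respects degenerate chains", {
  cfg <- sim_config(duration_s = 200)
  expect_identical(simulate_states(cfg, seed = 3), simulate_states(cfg, seed = 3))

  # absorbing chain: all rates zero -> constant sequence
  cfg0 <- sim_config(duration_s = 1800, rates = matrix(0, 3, 3))
  s0 <- simulate_states(cfg0, seed = 1)
  expect_length(s0, 1800)
  expect_length(unique(s0), 1)

  # deterministic cycle Q -> D -> R -> Q (per-frame probability 1)
  r <- matrix(0, 3, 3)
  r[1, 2] <- 1; r[2, 3] <- 1; r[3, 1] <- 1
  cyc <- simulate_states(sim_config(duration_s = 9, rates = r,
                                    emissions = default_emissions(0.05)),
                         seed = 2)
  lab <- as.character(cyc)
  expect_identical(lab[1:3], c(lab[4:6]))
  expect_identical(sort(unique(lab[1:3])), c("D", "Q", "R"))
  for (t in seq_len(8)) {
    expected_next <- c(Q = "D", D = "R", R = "Q")[lab[t]]
    expect_identical(lab[t + 1], unname(expected_next))
  }
})

test_that("invalid rate matrices are rejected with the offending state named", {
  r <- default_control_rates()
  r["D", "Q"] <- 1.5 # per-frame exit probability > 1 at 1 fps
  expect_error(sim_config(rates = r), "state D")
  expect_error(sim_config(rates = -r), "non-negative")
})

test_that("empirical per-frame transition frequencies match the generator", {
  cfg <- sim_config(duration_s = 1e5)
  s <- as.integer(simulate_states(cfg, seed = 41))
  P <- per_frame_matrix(cfg)
  from <- s[-length(s)]; to <- s[-1]
  for (i in 1:3) {
    n_i <- sum(from == i)
    for (j in 1:3) {
      p_hat <- sum(from == i & to == j) / n_i
      se <- sqrt(P[i, j] * (1 - P[i, j]) / n_i)
      expect_lt(abs(p_hat - P[i, j]), 3 * se + 1e-12,
                label = sprintf("|freq - p| for %d->%d", i, j))
    }
  }
})

test_that("simulated sequences pass a chi-square goodness-of-fit sweep", {
  # 20 seeds at alpha = 0.01: expect ~0.2 rejections; more than 2 is a red flag
  cfg <- sim_config(duration_s = 1e5)
  P <- per_frame_matrix(cfg)
  rejections <- 0
  for (seed in 1:20) {
    s <- as.integer(simulate_states(cfg, seed = seed))
    from <- s[-length(s)]; to <- s[-1]
    stat <- 0
    for (i in 1:3) {
      n_i <- sum(from == i)
      obs <- vapply(1:3, function(j) sum(from == i & to == j), 0)
      exp_ct <- n_i * P[i, ]
      stat <- stat + sum((obs - exp_ct)^2 / exp_ct)
    }
    p <- stats::pchisq(stat, df = 6, lower.tail = FALSE)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("long-run occupancy converges to the stationary distribution", {
  cfg <- sim_config(duration_s = 1e5)
  s <- as.integer(simulate_states(cfg, seed = 99))
  pi_true <- stationary_distribution(per_frame_matrix(cfg))
  # batch-means standard error: occupancy samples are strongly autocorrelated,
  # so a naive binomial SE would be far too small
  batches <- matrix(s, ncol = 20)
  for (k in 1:3) {
    fr <- colMeans(batches == k)
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - pi_true[k]), 3 * se,
              label = paste("occupancy of state", k))
  }
})

test_that("track kinematics honor the configured per-state model", {
  cfg <- sim_config(duration_s = 100, jitter_px = 0)
  # all-quiescent with zero jitter: the centroid never moves
  trk <- simulate_track(factor(rep("Q", 100), levels = state_levels()), cfg, seed = 1)
  expect_equal(diff(range(trk$x_px)), 0)
  expect_equal(diff(range(trk$y_px)), 0)

  # all-roaming, zero angular diffusion, fixed speed: collinear uniform steps
  em <- default_emissions(0.05)
  em$sd_log[3] <- 1e-12
  cfg2 <- sim_config(duration_s = 40, emissions = em, turn_sd_rad = 0,
                     arena_px = c(width = 2048, height = 2048))
  trk2 <- simulate_track(factor(rep("R", 40), levels = state_levels()), cfg2, seed = 5)
  steps <- cbind(diff(trk2$x_px), diff(trk2$y_px))
  expect_equal(sqrt(rowSums(steps^2)), rep(8, 39), tolerance = 1e-6)
  cross <- steps[-1, 1] * steps[-nrow(steps), 2] -
    steps[-1, 2] * steps[-nrow(steps), 1]
  expect_lt(max(abs(cross)), 1e-6) # collinear (no reflection reached)
})

test_that("per-state displacement log-speeds match the emission means", {
  # large arena: boundary reflections shorten displacements and would bias
  # the roaming comparison in a cramped field
  cfg <- sim_config(duration_s = 2e4,
                    arena_px = c(width = 4096, height = 4096))
  states <- simulate_states(cfg, seed = 8)
  trk <- simulate_track(states, cfg, seed = 9)
  sp <- compute_speeds(trk, window_s = 0)
  y <- log(sp$speed_px_s)
  st <- as.character(trk$true_state[-1])
  em <- emission_vectors_for_test(cfg)
  for (k in 1:3) {
    sel <- st == state_levels()[k]
    se <- sd(y[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(y[sel]) - em$mu[k]), 3 * se,
              label = paste("mean log-speed, state", state_levels()[k]))
  }
})

test_that("mock screens are reproducible, bookkept and validated", {
  cfg <- sim_config(duration_s = 100)
  eff <- list(effect_spec("a", n_control = 8, n_treated = 16),
              effect_spec("b", n_control = 3, n_treated = 4))
  scr <- simulate_screen(cfg, eff, seed = 7)
  expect_identical(scr$manifest$n_control, c(8L, 3L))
  expect_identical(scr$manifest$n_treated, c(16L, 4L))
  expect_identical(sum(scr$animals$role == "control"), 11L)
  scr2 <- simulate_screen(cfg, eff, seed = 7)
  expect_identical(scr$animals$data, scr2$animals$data)

  # multiplied rates breaking per-frame validity are rejected per gene
  bad <- effect_spec("boom", matrix(1e5, 3, 3))
  expect_error(simulate_screen(cfg, list(bad), seed = 1), "boom")
})

test_that("rate multipliers shift stationary occupancy as computed in closed form", {
  cfg <- sim_config()
  eff <- quiescence_destabilizing_effect()
  cfg_t <- cfg
  cfg_t$rates <- cfg$rates * `diag<-`(eff$rate_multipliers, 1)
  pi_c <- stationary_distribution(per_frame_matrix(cfg))
  pi_t <- stationary_distribution(per_frame_matrix(cfg_t))
  # doubling Q->D and halving D->Q must cut quiescence occupancy well below 80%
  expect_lt(pi_t[["Q"]] / pi_c[["Q"]], 0.8)
  # and the simulated occupancy agrees with the closed form
  s <- simulate_states(sim_config(duration_s = 5e4, rates = cfg_t$rates), seed = 13)
  expect_equal(mean(s == "Q"), pi_t[["Q"]], tolerance = 0.1)
})
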