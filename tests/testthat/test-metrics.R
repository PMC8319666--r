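test_that("percent time counts frames exactly and sums to one", {
  expect_equal(percent_time(rep("Q", 1800))$pct, c(100, 0, 0))
  pt <- percent_time(rep(c("Q", "D", "R"), c(900, 720, 180)))
  expect_equal(pt$pct, c(50, 40, 10))
  expect_equal(sum(pt$frac), 1, tolerance = 1e-12)
  expect_error(percent_time(character(0)), "no labeled frames")
})

test_that("percent time matches the stationary distribution on long runs", {
  cfg <- sim_config(duration_s = 1e5)
  s <- simulate_states(cfg, seed = 4)
  pt <- percent_time(s)
  pi_true <- stationary_distribution(per_frame_matrix(cfg))
  # batch-means SE (occupancy is autocorrelated)
  batches <- matrix(as.integer(s), ncol = 20)
  for (k in 1:3) {
    se <- sd(colMeans(batches == k)) / sqrt(20)
    expect_lt(abs(pt$frac[k] - pi_true[k]), 3 * se)
  }
})

test_that("transition rates are the exact MLE of the embedded chain", {
  tr <- transition_rates(c("D", "D", "Q", "Q", "Q", "D"), frame_rate_hz = 1)
  get <- function(f, t) tr$rate_per_s[tr$from == f & tr$to == t]
  expect_equal(get("D", "Q"), 0.5)   # 1 transition / 2 D-frames with successors
  expect_equal(get("Q", "D"), 1 / 3) # 1 transition / 3 Q-frames with successors
  expect_true(all(is.na(tr$rate_per_s[tr$from == "R"])))

  const <- transition_rates(rep("D", 50), frame_rate_hz = 2)
  expect_true(all(const$rate_per_s[!const$is_self & const$from == "D"] == 0))
  expect_equal(const$occupancy_s[const$from == "D"][1], 49 / 2)

  # conservation: rate x occupancy reproduces the integer counts exactly
  cfg <- sim_config(duration_s = 2000)
  s <- simulate_states(cfg, seed = 17)
  tr2 <- transition_rates(s, frame_rate_hz = 1)
  ok <- !is.na(tr2$rate_per_s) & !tr2$is_self
  expect_identical(round(tr2$rate_per_s[ok] * tr2$occupancy_s[ok]),
                   as.numeric(tr2$n_transitions[ok]))
  # outgoing transitions cannot exceed occupancy frames
  agg <- tapply(tr2$n_transitions[!tr2$is_self], tr2$from[!tr2$is_self], sum)
  occ_frames <- tapply(tr2$occupancy_s, tr2$from, max) * 1
  expect_true(all(agg <= occ_frames))
})

test_that("estimated rates recover the generating control rates", {
  cfg <- sim_config(duration_s = 1e5) # includes D->R 0.001, Q->R 0.0002 per s
  s <- simulate_states(cfg, seed = 7)
  tr <- transition_rates(s, frame_rate_hz = 1)
  tr <- tr[!tr$is_self, ]
  truth <- cfg$rates[cbind(as.integer(tr$from), as.integer(tr$to))]
  se <- sqrt(pmax(tr$n_transitions, 1)) / tr$occupancy_s # Poisson SE
  expect_true(all(abs(tr$rate_per_s - truth) <= 3 * se))
})

test_that("no transitions are counted across segment gaps", {
  d <- tibble::tibble(
    label = c("Q", "Q", "D", "D"),
    segment = c(1L, 1L, 2L, 2L),
    time_s = c(0, 1, 10, 11)
  )
  tr <- transition_rates(d, frame_rate_hz = 1)
  expect_identical(tr$n_transitions[tr$from == "Q" & tr$to == "D"], 0L)
  expect_identical(tr$n_transitions[tr$from == "Q" & tr$to == "Q"], 1L)
  expect_identical(tr$n_transitions[tr$from == "D" & tr$to == "D"], 1L)
})

test_that("bout durations partition the session and flag censoring", {
  b <- bout_durations(rep("Q", 1800), frame_rate_hz = 1)
  expect_identical(nrow(b), 1L)
  expect_equal(b$duration_s, 1800)
  expect_true(b$censored_left & b$censored_right)

  alt <- bout_durations(rep(c("Q", "D"), 5), frame_rate_hz = 1)
  expect_identical(nrow(alt), 10L)
  expect_equal(alt$duration_s, rep(1, 10))
  expect_identical(sum(alt$censored), 2L)
  expect_identical(as.character(alt$state[1]), "Q")

  cfg <- sim_config(duration_s = 5000)
  s <- simulate_states(cfg, seed = 23)
  b2 <- bout_durations(s, frame_rate_hz = 1)
  expect_equal(sum(b2$n_frames), 5000) # bouts partition all frames
})

test_that("mean uncensored bout duration matches reciprocal exit rates", {
  cfg <- sim_config(duration_s = 1e5)
  s <- simulate_states(cfg, seed = 29)
  b <- bout_durations(s, frame_rate_hz = 1)
  exit <- rowSums(cfg$rates)
  for (st in c("Q", "D")) { # roaming handled in the pooled acceptance check
    mb <- mean(b$duration_s[b$state == st & !b$censored])
    expect_equal(mb, 1 / exit[[st]], tolerance = 0.1)
  }
})

test_that("behavior_summary is consistent with its components", {
  cfg <- sim_config(duration_s = 1500)
  p <- hmm_params(rep(1 / 3, 3), per_frame_matrix(cfg),
                  emission_vectors_for_test(cfg)$mu,
                  emission_vectors_for_test(cfg)$sd)
  sp1 <- simulate_speeds(simulate_states(cfg, seed = 61), cfg, seed = 62)
  sp1$animal_id <- "a1"
  sp2 <- simulate_speeds(simulate_states(cfg, seed = 63), cfg, seed = 64)
  sp2$animal_id <- "a2"
  d <- decode_states(p, dplyr::bind_rows(sp1, sp2))
  sm <- behavior_summary(d, frame_rate_hz = 1)
  expect_identical(sm$animal_id, c("a1", "a2"))
  expect_equal(sm$pct_R + sm$pct_D + sm$pct_Q, c(100, 100), tolerance = 1e-9)
  pt1 <- percent_time(d[d$animal_id == "a1", ])
  expect_equal(sm$pct_Q[1], pt1$pct[1])
})

test_that("percent time is invariant to segment splits at non-transition frames", {
  s <- rep(c("Q", "D", "Q"), c(40, 30, 30))
  whole <- percent_time(s)
  split_df <- tibble::tibble(label = s, segment = rep(c(1L, 2L), c(55, 45)),
                             time_s = seq_along(s) - 1)
  expect_equal(percent_time(split_df)$pct, whole$pct)
})
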