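fake_summary <- function(ids, pct_q, pct_d = 100 - pct_q - pct_r, pct_r = 1,
                         rate_dq = 0.02, rate_qd = 0.02) {
  tibble::tibble(
    animal_id = ids, n_valid_frames = 1800L,
    pct_R = pct_r, pct_D = pct_d, pct_Q = pct_q,
    rate_QD = rate_qd, rate_QR = 2e-4, rate_DQ = rate_dq, rate_DR = 1e-3,
    rate_RQ = 5e-3, rate_RD = 5e-2
  )
}

test_that("normalization to the concurrent control is a ratio of group means", {
  ctl <- fake_summary(paste0("c", 1:5), pct_q = c(48, 50, 52, 49, 51))
  same <- normalize_to_control(ctl, ctl)
  expect_true(all(same$normalized[!same$unstable] == 1))

  trt <- fake_summary(paste0("t", 1:4), pct_q = c(18, 20, 22, 20))
  nm <- normalize_to_control(trt, ctl)
  expect_equal(nm$normalized[nm$metric == "pct_Q"], 0.4)

  # scale equivariance: common positive rescaling leaves ratios unchanged
  sc <- function(s, c) { s[names(s) %in% quiescr:::SCREEN_METRICS] <-
    s[names(s) %in% quiescr:::SCREEN_METRICS] * c; s }
  nm2 <- normalize_to_control(sc(trt, 3.7), sc(ctl, 3.7))
  expect_equal(nm2$normalized, nm$normalized)

  # near-zero control means are flagged unstable, not reported as huge ratios
  ctl0 <- fake_summary(paste0("c", 1:5), pct_q = 50, pct_r = 0.1)
  trt0 <- fake_summary(paste0("t", 1:4), pct_q = 50, pct_r = 5)
  nm0 <- normalize_to_control(trt0, ctl0)
  expect_true(nm0$unstable[nm0$metric == "pct_R"])
  expect_true(is.na(nm0$normalized[nm0$metric == "pct_R"]))
  expect_error(normalize_to_control(trt0[0, ], ctl0), "non-empty")
})

test_that("pooled t-test matches the hand-computed Student formula", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  res <- two_sample_t_test(x, y)
  # independent evaluation of the pooled-variance formula + t distribution
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_ref <- 2 * pt(-abs(t_ref), df = 4)
  expect_equal(res$t, t_ref, tolerance = 1e-12)
  expect_identical(res$df, 4)
  expect_equal(res$p_value, p_ref, tolerance = 1e-12)

  same <- two_sample_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # degenerate zero-variance cases
  eq <- two_sample_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(eq$p_value, 1)
  ne <- two_sample_t_test(c(2, 2, 2), c(3, 3))
  expect_equal(ne$p_value, 0)
  expect_true(ne$degenerate)

  # power sanity: a 3-pooled-SD shift at large n is overwhelmingly significant
  set.seed(1)
  big <- two_sample_t_test(rnorm(60, 3), rnorm(60, 0))
  expect_lt(big$p_value, 1e-3)
  expect_error(two_sample_t_test(1, c(1, 2)), "at least 2")
})

test_that("Bonferroni threshold is exact internally and rounded for display", {
  b <- bonferroni_threshold(0.05, 56)
  expect_equal(b$exact, 0.05 / 56, tolerance = 1e-15)
  expect_identical(b$display, 0.0009)
  expect_identical(bonferroni_threshold(0.05, 1)$display, 0.05)
  expect_identical(bonferroni_threshold(0.05, 2)$display, 0.025)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
  expect_error(bonferroni_threshold(1.2, 5), "alpha")
})

test_that("hit classification applies both cutoff rules and is monotone", {
  expect_identical(as.character(classify_hits(1.0, "ratio_band")), "neutral")
  expect_identical(as.character(classify_hits(1.0, "ratio_asym")), "neutral")
  expect_identical(as.character(classify_hits(1.94, "ratio_asym")), "enhanced")
  expect_identical(as.character(classify_hits(0.75, "ratio_band")), "reduced")
  expect_identical(as.character(classify_hits(0.75, "ratio_asym")), "neutral")
  expect_identical(as.character(classify_hits(NA_real_)), "unresolved")

  grid <- seq(0.05, 2.5, by = 0.05)
  for (rule in c("ratio_band", "ratio_asym")) {
    cls <- as.integer(factor(classify_hits(grid, rule),
                             levels = c("reduced", "neutral", "enhanced")))
    expect_true(all(diff(cls) >= 0), info = paste("monotone under", rule))
  }
})

test_that("screen_report assembles per-gene rows with the right family size", {
  ctl <- fake_summary(paste0("c", 1:5), pct_q = c(48, 50, 52, 49, 51))
  trt <- fake_summary(paste0("t", 1:4), pct_q = c(18, 20, 22, 20))
  sm <- dplyr::bind_rows(
    dplyr::mutate(ctl, gene = "g1", role = "control"),
    dplyr::mutate(trt, gene = "g1", role = "treated"),
    dplyr::mutate(fake_summary(paste0("d", 1:4), pct_q = c(49, 50, 51, 50)),
                  gene = "g2", role = "control"),
    dplyr::mutate(fake_summary(paste0("e", 1:4), pct_q = c(50, 49, 51, 50)),
                  gene = "g2", role = "treated")
  )
  rep <- screen_report(sm)
  expect_identical(rep$gene, c("g1", "g2"))
  expect_identical(attr(rep, "family_size"), 4L) # 2 genes x 2 states
  expect_equal(rep$norm_pct_Q, c(0.4, 1), tolerance = 1e-12)
  expect_identical(as.character(rep$classification), c("reduced", "neutral"))
  expect_identical(rep$n_control, c(5L, 4L))
  expect_identical(rep$n_treated, c(4L, 4L))

  # manifest order is preserved
  rep2 <- screen_report(sm, manifest = tibble::tibble(gene = c("g2", "g1")))
  expect_identical(rep2$gene, c("g2", "g1"))

  # orphan treated group rejected by name
  orphan <- sm[!(sm$gene == "g2" & sm$role == "control"), ]
  expect_error(screen_report(orphan), "g2")

  gl <- glance(rep)
  expect_identical(gl$family_size, 4L)
  td <- tidy(rep)
  expect_identical(nrow(td), 2L * 9L)
})

test_that("a 28-gene family reproduces the screen-wide threshold", {
  sm <- purrr::map_dfr(1:28, function(g) {
    dplyr::bind_rows(
      dplyr::mutate(fake_summary(paste0("g", g, "c", 1:3),
                                 pct_q = c(49, 50, 51)),
                    gene = paste0("gene", g), role = "control"),
      dplyr::mutate(fake_summary(paste0("g", g, "t", 1:3),
                                 pct_q = c(48, 50, 52)),
                    gene = paste0("gene", g), role = "treated")
    )
  })
  rep <- screen_report(sm)
  expect_identical(attr(rep, "family_size"), 56L)
  expect_identical(attr(rep, "alpha_display"), 0.0009)
})
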