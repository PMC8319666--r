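SCREEN_METRICS <- c("pct_R", "pct_D", "pct_Q",
                    "rate_QD", "rate_QR", "rate_DQ", "rate_DR",
                    "rate_RQ", "rate_RD")

#' Summarize a group of animals
#'
#' Mean, standard error and n for each per-animal metric of a
#' [behavior_summary()] table. SEM is `NA` for groups of one.
#'
#' @param summaries Per-animal summary tibble.
#' @return Tibble: `metric`, `mean`, `sem`, `n`.
#' @export
summarize_group <- function(summaries) {
  metrics <- intersect(SCREEN_METRICS, names(summaries))
  purrr::map_dfr(metrics, function(m) {
    v <- summaries[[m]]
    v <- v[!is.na(v)]
    tibble(metric = m,
           mean = if (length(v)) mean(v) else NA_real_,
           sem = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
           n = length(v))
  })
}

#' Normalize a treated group to its concurrent control
#'
#' Each metric is the ratio of the treated group's arithmetic mean to the
#' concurrent control group's mean (ratio of means, dimensionless). Ratios
#' whose control mean falls below a stability floor (0.5 percentage points for
#' percent-time metrics, 1e-4 s^-1 for rates, by default) are flagged
#' `unstable` and the ratio is reported `NA` rather than as an extreme value:
#' near-zero control roaming would otherwise produce meaningless huge ratios.
#'
#' @param treated,control Per-animal [behavior_summary()] tibbles.
#' @param floor_pct,floor_rate Control-mean floors for percent-time and rate
#'   metrics.
#' @return Tibble: `metric`, `treated_mean`, `control_mean`, `normalized`,
#'   `unstable`.
#' @export
normalize_to_control <- function(treated, control,
                                 floor_pct = 0.5, floor_rate = 1e-4) {
  if (nrow(treated) == 0 || nrow(control) == 0) {
    stop("treated and control groups must be non-empty", call. = FALSE)
  }
  ts <- summarize_group(treated)
  cs <- summarize_group(control)
  if (!identical(ts$metric, cs$metric)) {
    stop("treated and control groups carry different metric sets", call. = FALSE)
  }
  floor_of <- ifelse(grepl("^pct_", ts$metric), floor_pct, floor_rate)
  unstable <- is.na(cs$mean) | abs(cs$mean) < floor_of
  tibble(
    metric = ts$metric,
    treated_mean = ts$mean,
    control_mean = cs$mean,
    normalized = ifelse(unstable, NA_real_, ts$mean / cs$mean),
    unstable = unstable
  )
}

#' Pooled-variance two-sample Student's t-test
#'
#' Classical equal-variance two-sided t-test with `df = n1 + n2 - 2`, the
#' test applied to per-animal percent-time values in the screen. Degenerate
#' inputs (zero pooled variance) give p = 1 when the means agree and p = 0
#' (flagged) when they differ.
#'
#' @param treated,control Numeric vectors of per-animal metric values
#'   (>= 2 each).
#' @return Tibble: `t`, `df`, `p_value`, `degenerate`.
#' @export
#' @examples
#' two_sample_t_test(c(1, 2, 3), c(2, 3, 4))
two_sample_t_test <- function(treated, control) {
  x <- treated[!is.na(treated)]
  y <- control[!is.na(control)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  df <- length(x) + length(y) - 2
  pooled <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) / df
  if (pooled <= 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble(t = 0, df = df, p_value = 1, degenerate = FALSE))
    }
    return(tibble(t = sign(mean(x) - mean(y)) * Inf, df = df, p_value = 0,
                  degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE)
}

#' Bonferroni per-comparison threshold
#'
#' Divides the family-wise level by the number of comparisons. The exact value
#' is kept internally; the display value is rounded to 4 decimals (0.05/56
#' displays as 0.0009).
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (positive integer).
#' @return List with `exact` and `display`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 56)$display
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || m < 1 || abs(m - round(m)) > 1e-9) {
    stop("m must be a positive integer", call. = FALSE)
  }
  exact <- alpha / m
  list(exact = exact, display = round(exact, 4))
}

#' Classify a knockdown by its normalized quiescence
#'
#' Two rules from the screen workflow: `ratio_band` calls a gene reduced or
#' enhanced when normalized quiescence leaves a symmetric band of +/- `band`
#' around 1 (default 20%); `ratio_asym` uses asymmetric cutoffs (default
#' reduced at <= 0.6, enhanced at >= 1.7). Missing values classify as
#' `unresolved`.
#'
#' @param normalized_q Numeric vector of normalized quiescence values.
#' @param rule `"ratio_band"` or `"ratio_asym"`.
#' @param band Half-width of the neutral band for `ratio_band`.
#' @param cutoffs Length-2 vector `c(reduced, enhanced)` for `ratio_asym`.
#' @return Factor with levels `reduced`, `neutral`, `enhanced`, `unresolved`.
#' @export
#' @examples
#' classify_hits(c(0.75, 1.0, 1.94), rule = "ratio_asym")
#' classify_hits(c(0.75, 1.0, 1.94), rule = "ratio_band")
classify_hits <- function(normalized_q, rule = c("ratio_band", "ratio_asym"),
                          band = 0.20, cutoffs = c(0.6, 1.7)) {
  rule <- match.arg(rule)
  lv <- c("reduced", "neutral", "enhanced", "unresolved")
  out <- rep("neutral", length(normalized_q))
  if (rule == "ratio_band") {
    out[normalized_q < 1 - band] <- "reduced"
    out[normalized_q > 1 + band] <- "enhanced"
  } else {
    out[normalized_q <= cutoffs[1]] <- "reduced"
    out[normalized_q >= cutoffs[2]] <- "enhanced"
  }
  out[is.na(normalized_q)] <- "unresolved"
  factor(out, levels = lv)
}

#' Build the screen table
#'
#' One row per gene: metrics normalized to the concurrent control, raw
#' two-sided p-values for percent dwelling and percent quiescence, the
#' Bonferroni-corrected per-comparison threshold, the ratio classification of
#' quiescence, and group sizes. The Bonferroni family defaults to
#' (number of genes) x 2, one comparison each for dwelling and quiescence;
#' raw p-values are compared against `alpha / m` rather than adjusted.
#'
#' @param summaries Per-animal [behavior_summary()] table carrying `gene` and
#'   `role` (`"control"`/`"treated"`) columns.
#' @param manifest Optional tibble with a `gene` column fixing row order
#'   (default: order of first appearance in `summaries`).
#' @param alpha Family-wise level (default 0.05).
#' @param family_size Number of comparisons `m`; default `2 * n_genes`.
#' @param rule,band,cutoffs Passed to [classify_hits()].
#' @param floor_pct,floor_rate Passed to [normalize_to_control()].
#' @return Tibble of class `quiescr_screen`: `gene`, `norm_pct_R/D/Q`,
#'   `norm_rate_*`, `p_pct_D`, `p_pct_Q`, `classification`, `significant_q`,
#'   `n_control`, `n_treated`, plus attributes `alpha`, `family_size`,
#'   `alpha_corrected` (exact) and `alpha_display`.
#' @export
screen_report <- function(summaries, manifest = NULL, alpha = 0.05,
                          family_size = NULL,
                          rule = c("ratio_band", "ratio_asym"),
                          band = 0.20, cutoffs = c(0.6, 1.7),
                          floor_pct = 0.5, floor_rate = 1e-4) {
  rule <- match.arg(rule)
  stopifnot(all(c("gene", "role") %in% names(summaries)))
  genes <- if (!is.null(manifest)) as.character(manifest$gene)
           else unique(summaries$gene)
  missing_genes <- setdiff(unique(summaries$gene), genes)
  if (length(missing_genes) > 0) {
    stop("summaries contain gene(s) absent from the manifest: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  if (is.null(family_size)) family_size <- 2L * length(genes)
  thr <- bonferroni_threshold(alpha, family_size)
  rows <- purrr::map_dfr(genes, function(g) {
    d <- summaries[summaries$gene == g, ]
    trt <- d[d$role == "treated", ]
    ctl <- d[d$role == "control", ]
    if (nrow(ctl) == 0) {
      stop("treated group '", g, "' has no concurrent control", call. = FALSE)
    }
    if (nrow(trt) == 0) {
      stop("gene '", g, "' has no treated animals", call. = FALSE)
    }
    nm <- normalize_to_control(trt, ctl, floor_pct, floor_rate)
    norm <- setNames(rep(NA_real_, length(SCREEN_METRICS)),
                     paste0("norm_", SCREEN_METRICS))
    norm[paste0("norm_", nm$metric)] <- nm$normalized
    p_d <- two_sample_t_test(trt$pct_D, ctl$pct_D)$p_value
    p_q <- two_sample_t_test(trt$pct_Q, ctl$pct_Q)$p_value
    nq <- norm[["norm_pct_Q"]]
    dplyr::bind_cols(
      tibble(gene = g),
      as_tibble(as.list(norm[c("norm_pct_R", "norm_pct_D", "norm_pct_Q",
                               "norm_rate_QD", "norm_rate_QR", "norm_rate_DQ",
                               "norm_rate_DR", "norm_rate_RQ", "norm_rate_RD")])),
      tibble(p_pct_D = p_d, p_pct_Q = p_q,
             classification = classify_hits(nq, rule, band, cutoffs),
             significant_q = is.finite(p_q) & p_q < thr$exact,
             n_control = nrow(ctl), n_treated = nrow(trt))
    )
  })
  attr(rows, "alpha") <- alpha
  attr(rows, "family_size") <- as.integer(family_size)
  attr(rows, "alpha_corrected") <- thr$exact
  attr(rows, "alpha_display") <- thr$display
  attr(rows, "rule") <- rule
  class(rows) <- c("quiescr_screen", class(rows))
  rows
}

#' @export
print.quiescr_screen <- function(x, ...) {
  cat(sprintf(
    "<quiescr_screen> %d gene(s); alpha = %g over %d comparisons -> threshold %g (displayed %g)\n",
    nrow(x), attr(x, "alpha"), attr(x, "family_size"),
    attr(x, "alpha_corrected"), attr(x, "alpha_display")))
  NextMethod()
}
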