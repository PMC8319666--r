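#' Construct and validate a three-state HMM parameter set
#'
#' The model observes `y = log(speed + epsilon)` and emits from a univariate
#' Gaussian per hidden state. States are kept in canonical order: after
#' fitting, states are relabeled so that emission means ascend
#' quiescence < dwelling < roaming.
#'
#' @param pi Initial-state probabilities (length 3, sums to 1).
#' @param A 3x3 per-frame transition matrix (rows sum to 1).
#' @param mu,sigma Per-state emission mean and sd on the log-speed scale.
#' @param epsilon Speed floor (px/s) inside the log transform (default 0.01).
#' @return Object of class `quiescr_hmm`.
#' @export
#' @examples
#' hmm_params(rep(1/3, 3), diag(3) * 0.9 + 0.05, c(-3, 0, 2), c(0.5, 0.5, 0.5))
hmm_params <- function(pi, A, mu, sigma, epsilon = 0.01) {
  obj <- structure(
    list(pi = as.numeric(pi), A = unname(as.matrix(A)), mu = as.numeric(mu),
         sigma = as.numeric(sigma), epsilon = epsilon,
         states = STATES, logLik = NA_real_, trace = numeric(),
         n_iter = NA_integer_, converged = NA, n_obs = NA_integer_,
         n_seq = NA_integer_),
    class = "quiescr_hmm"
  )
  validate_hmm(obj)
  obj
}

validate_hmm <- function(p) {
  K <- length(p$mu)
  if (K != 3 || length(p$sigma) != 3 || length(p$pi) != 3 ||
      !identical(dim(p$A), c(3L, 3L))) {
    stop("model must have exactly 3 states", call. = FALSE)
  }
  if (any(p$pi < -1e-12) || abs(sum(p$pi) - 1) > 1e-8) {
    stop("pi must be a probability vector", call. = FALSE)
  }
  if (any(p$A < -1e-12) || any(abs(rowSums(p$A) - 1) > 1e-8)) {
    stop("rows of A must sum to 1 with non-negative entries", call. = FALSE)
  }
  if (any(!is.finite(p$mu))) stop("emission means must be finite", call. = FALSE)
  if (any(p$sigma <= 0)) stop("emission sds must be positive", call. = FALSE)
  invisible(p)
}

#' Map state indices to behavioral labels by emission mean
#'
#' The slowest state is quiescence, the middle one dwelling, the fastest
#' roaming. Exactly equal means are unidentifiable and rejected.
#'
#' @param mu Numeric vector of 3 emission means (log px/s).
#' @return Character vector: label of each state index.
#' @export
#' @examples
#' label_states(c(-3, 0, 2))  # "Q" "D" "R"
#' label_states(c(2, -3, 0))  # "R" "Q" "D"
label_states <- function(mu) {
  if (inherits(mu, "quiescr_hmm")) mu <- mu$mu
  if (length(mu) != 3 || any(!is.finite(mu))) {
    stop("need 3 finite emission means", call. = FALSE)
  }
  if (anyDuplicated(mu)) {
    stop("emission means are exactly equal: states unidentifiable", call. = FALSE)
  }
  lab <- character(3)
  lab[order(mu)] <- STATES
  lab
}

# reorder a parameter set so state order is Q, D, R (ascending mu)
relabel_hmm <- function(p) {
  o <- order(p$mu)
  p$pi <- p$pi[o]
  p$A <- p$A[o, o, drop = FALSE]
  p$mu <- p$mu[o]
  p$sigma <- p$sigma[o]
  p$states <- STATES
  p
}

# emission density matrix (linear scale) for observations y
emission_density <- function(p, y, log = FALSE) {
  B <- vapply(1:3, function(k) dnorm(y, p$mu[k], p$sigma[k], log = log),
              numeric(length(y)))
  B <- matrix(B, ncol = 3)
  if (!log) B[B < 1e-300] <- 1e-300
  B
}

#' Forward log-likelihood of a log-speed sequence
#'
#' Scaled forward recursion: returns `log P(y | params)`.
#'
#' @param params A [hmm_params()] object.
#' @param observations Numeric vector of log-speed observations
#'   (`log(speed + epsilon)`).
#' @return Finite scalar log-likelihood.
#' @export
hmm_loglik <- function(params, observations) {
  validate_hmm(params)
  y <- as.numeric(observations)
  if (length(y) == 0) stop("observations must be non-empty", call. = FALSE)
  cpp_forward_loglik(emission_density(params, y), params$pi, params$A)
}

# normalize the many accepted speed inputs to a named list of speed vectors
as_speed_sequences <- function(speeds) {
  if (is.numeric(speeds)) return(list(seq1 = speeds))
  if (is.data.frame(speeds)) {
    stopifnot("speed_px_s" %in% names(speeds))
    keys <- list()
    if ("animal_id" %in% names(speeds)) keys$animal <- speeds$animal_id
    if ("segment" %in% names(speeds)) keys$segment <- speeds$segment
    if (length(keys) == 0) return(list(seq1 = speeds$speed_px_s))
    f <- interaction(keys, drop = TRUE, lex.order = TRUE)
    return(split(speeds$speed_px_s, f))
  }
  if (is.list(speeds)) {
    out <- purrr::map(speeds, function(s) {
      if (is.data.frame(s)) s$speed_px_s else as.numeric(s)
    })
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  stop("unsupported speeds input", call. = FALSE)
}

quantile_init <- function(y_all, epsilon) {
  qs <- quantile(y_all, c(1 / 3, 2 / 3), names = FALSE)
  grp <- findInterval(y_all, qs) + 1L
  mu <- vapply(1:3, function(g) mean(y_all[grp == g]), 0)
  sg <- vapply(1:3, function(g) {
    s <- sd(y_all[grp == g])
    if (!is.finite(s)) s <- 0
    max(s, 0.05)
  }, 0)
  mu[!is.finite(mu)] <- mean(y_all) # empty tercile (heavily tied data)
  if (anyDuplicated(mu)) mu <- sort(mu) + c(-1e-6, 0, 1e-6)
  A <- matrix(0.025, 3, 3); diag(A) <- 0.95
  hmm_params(rep(1 / 3, 3), A, mu, sg, epsilon = epsilon)
}

#' Fit the three-state HMM by Baum-Welch
#'
#' Multi-sequence expectation-maximization on log-speed observations, pooling
#' expected counts across animals/segments. The recursions are scaled
#' (numerically exact in log space); the total log-likelihood is non-decreasing
#' across iterations. After convergence, states are relabeled by ascending
#' emission mean so state 1 is quiescence, 2 dwelling, 3 roaming.
#'
#' Deterministic "quantile" initialization splits the pooled log-speeds at the
#' 33rd/67th percentiles and uses per-tercile means/sds, with 0.95
#' self-transitions and a uniform initial distribution.
#'
#' @param speeds A speed tibble from [compute_speeds()] (split by animal and
#'   segment), a list of numeric speed vectors, or a single numeric vector.
#'   Units px/s.
#' @param init `"quantile"` or a [hmm_params()] object to start from.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood change for convergence (default 1e-6).
#' @param epsilon Speed floor in `log(speed + epsilon)` (default 0.01 px/s).
#' @param sigma_floor Lower bound on emission sds (default 1e-3), preventing
#'   variance collapse onto single observations.
#' @return A `quiescr_hmm` with `logLik`, the per-iteration `trace`,
#'   `n_iter`, `converged`, `n_obs` and `n_seq` filled in.
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 300)
#' sp <- simulate_speeds(simulate_states(cfg, 1), cfg, seed = 2)
#' fit <- fit_hmm(sp$speed_px_s, max_iter = 50)
#' fit$mu
fit_hmm <- function(speeds, init = "quantile", max_iter = 500, tol = 1e-6,
                    epsilon = 0.01, sigma_floor = 1e-3) {
  seqs <- as_speed_sequences(speeds)
  short <- vapply(seqs, function(s) length(s) < 2, TRUE)
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than 2 observations excluded",
            call. = FALSE)
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0) stop("no usable sequences (all shorter than 2)", call. = FALSE)
  ys <- purrr::map(seqs, function(s) log(s + epsilon))
  n_obs <- sum(lengths(ys))
  n_free <- 2 + 6 + 6 # pi (2 free) + A rows (2 each) + emissions (mu, sigma)
  if (n_obs < 30 * n_free) {
    warning("only ", n_obs, " observations for ", n_free,
            " free parameters; estimates may be unstable", call. = FALSE)
  }
  p <- if (inherits(init, "quiescr_hmm")) {
    init$epsilon <- epsilon
    validate_hmm(init)
    init
  } else if (identical(init, "quantile")) {
    quantile_init(unlist(ys, use.names = FALSE), epsilon)
  } else {
    stop("init must be \"quantile\" or a quiescr_hmm object", call. = FALSE)
  }
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll <- 0
    pi_acc <- numeric(3)
    xi_acc <- matrix(0, 3, 3)
    g_acc <- numeric(3)     # sum of gammas over all frames
    gy_acc <- numeric(3)    # sum gamma * y
    gyy_acc <- numeric(3)   # sum gamma * y^2
    gout_acc <- numeric(3)  # sum of gammas excluding last frame (A denominator)
    for (y in ys) {
      B <- emission_density(p, y)
      fb <- cpp_forward_backward(B, p$pi, p$A)
      ll <- ll + fb$loglik
      g <- fb$gamma
      pi_acc <- pi_acc + g[1, ]
      xi_acc <- xi_acc + fb$xi
      g_acc <- g_acc + colSums(g)
      gy_acc <- gy_acc + colSums(g * y)
      gyy_acc <- gyy_acc + colSums(g * y^2)
      gout_acc <- gout_acc + colSums(g[-nrow(g), , drop = FALSE])
    }
    trace <- c(trace, ll)
    if (it > 1) {
      rel <- abs(ll - trace[it - 1]) / (1 + abs(ll))
      if (rel < tol) { converged <- TRUE; break }
    }
    # M-step
    p$pi <- pi_acc / sum(pi_acc)
    A_new <- xi_acc / pmax(gout_acc, 1e-300)
    # guard empty states: keep previous row
    for (k in 1:3) {
      if (gout_acc[k] < 1e-8) A_new[k, ] <- p$A[k, ]
      A_new[k, ] <- pmax(A_new[k, ], 0)
      A_new[k, ] <- A_new[k, ] / sum(A_new[k, ])
    }
    p$A <- A_new
    for (k in 1:3) {
      if (g_acc[k] > 1e-8) {
        m <- gy_acc[k] / g_acc[k]
        v <- gyy_acc[k] / g_acc[k] - m^2
        p$mu[k] <- m
        p$sigma[k] <- max(sqrt(max(v, 0)), sigma_floor)
      }
    }
  }
  p <- relabel_hmm(p)
  p$logLik <- trace[length(trace)]
  p$trace <- trace
  p$n_iter <- length(trace)
  p$converged <- converged
  p$n_obs <- n_obs
  p$n_seq <- length(ys)
  p
}

#' Decode behavioral states from a speed series
#'
#' Viterbi decoding (most probable state path, ties broken toward the lowest
#' state index, i.e. Q before D before R) plus forward-backward posterior
#' probabilities, per contiguous segment. No transition is inferred across a
#' segment split.
#'
#' @param params Fitted [hmm_params()] / [fit_hmm()] model.
#' @param speeds Speed tibble from [compute_speeds()], or a numeric speed
#'   vector (px/s) treated as a single segment.
#' @return Tibble of class `quiescr_states`: `animal_id`, `segment`, `frame`,
#'   `time_s`, `label` (factor Q/D/R), `p_Q`, `p_D`, `p_R`, with the total
#'   observation log-likelihood in attribute `"log_likelihood"`.
#' @export
decode_states <- function(params, speeds) {
  validate_hmm(params)
  if (is.numeric(speeds)) {
    speeds <- tibble(animal_id = "worm", segment = 1L,
                     frame = seq_along(speeds) - 1L,
                     time_s = as.numeric(seq_along(speeds) - 1L),
                     speed_px_s = as.numeric(speeds))
  }
  stopifnot("speed_px_s" %in% names(speeds))
  if (!"animal_id" %in% names(speeds)) speeds$animal_id <- "worm"
  if (!"segment" %in% names(speeds)) speeds$segment <- 1L
  if (!"frame" %in% names(speeds)) speeds$frame <- seq_len(nrow(speeds)) - 1L
  if (!"time_s" %in% names(speeds)) speeds$time_s <- as.numeric(speeds$frame)
  logpi <- log(pmax(params$pi, 1e-300))
  logA <- log(pmax(params$A, 1e-300))
  total_ll <- 0
  out <- speeds |>
    dplyr::group_by(.data$animal_id, .data$segment) |>
    dplyr::group_modify(function(d, key) {
      y <- log(d$speed_px_s + params$epsilon)
      logB <- emission_density(params, y, log = TRUE)
      vit <- cpp_viterbi(logB, logpi, logA)
      B <- emission_density(params, y)
      fb <- cpp_forward_backward(B, params$pi, params$A)
      total_ll <<- total_ll + fb$loglik
      tibble(
        frame = d$frame, time_s = d$time_s,
        label = factor(STATES[vit$path], levels = STATES),
        p_Q = fb$gamma[, 1], p_D = fb$gamma[, 2], p_R = fb$gamma[, 3]
      )
    }) |>
    dplyr::ungroup()
  attr(out, "log_likelihood") <- total_ll
  class(out) <- c("quiescr_states", class(out))
  out
}

#' @export
print.quiescr_hmm <- function(x, ...) {
  cat("<quiescr_hmm> 3-state Gaussian HMM on log(speed + ", x$epsilon, ")\n",
      sep = "")
  tab <- data.frame(state = x$states, pi = round(x$pi, 4),
                    mu_log = round(x$mu, 4), sd_log = round(x$sigma, 4))
  print(tab, row.names = FALSE)
  cat("A (per-frame):\n")
  A <- round(x$A, 5); dimnames(A) <- list(x$states, x$states)
  print(A)
  if (is.finite(x$logLik)) {
    cat(sprintf("logLik %.3f after %d iteration(s); converged: %s\n",
                x$logLik, x$n_iter, x$converged))
  }
  invisible(x)
}
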