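# Exhaustive-enumeration HMM oracle: sums (and maximizes) over all K^n hidden
# paths directly from the model definition, independent of the package's
# recursions. Only usable for tiny n.
brute_force_hmm <- function(params, y) {
  K <- length(params$mu)
  n <- length(y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- apply(paths, 1, function(z) {
    v <- log(params$pi[z[1]]) +
      dnorm(y[1], params$mu[z[1]], params$sigma[z[1]], log = TRUE)
    if (n > 1) {
      for (t in 2:n) {
        v <- v + log(params$A[z[t - 1], z[t]]) +
          dnorm(y[t], params$mu[z[t]], params$sigma[z[t]], log = TRUE)
      }
    }
    v
  })
  M <- max(lp)
  list(loglik = M + log(sum(exp(lp - M))),
       best_path = paths[which.max(lp), ],
       best_logprob = M)
}

# Random valid 3-state parameter set (distinct emission means almost surely)
random_hmm_params <- function() {
  A <- matrix(rgamma(9, 1), 3)
  A <- A / rowSums(A)
  pi0 <- rgamma(3, 1)
  hmm_params(pi0 / sum(pi0), A, sort(rnorm(3, sd = 2)), runif(3, 0.3, 1.5))
}

# Speeds whose log(speed + epsilon) equal the given observations exactly
speeds_for_obs <- function(y, epsilon = 0.01) exp(y) - epsilon

emission_vectors_for_test <- function(cfg) quiescr:::emission_vectors(cfg)

# Control configuration used across tests (the assay's defaults)
control_config <- function(duration_s = 1800) sim_config(duration_s = duration_s)

# Effect used in the knockdown-detection checks: quiescence-to-dwelling rate
# doubled, dwelling-to-quiescence halved (destabilizes quiescence)
quiescence_destabilizing_effect <- function(n_treated = 16, n_control = 8) {
  m <- matrix(1, 3, 3)
  m[1, 2] <- 2   # Q -> D
  m[2, 1] <- 0.5 # D -> Q
  effect_spec("kd", m, n_treated = n_treated, n_control = n_control)
}

# Per-animal percent-time summary straight from ground-truth state sequences
# (no decoding), for screen-statistics checks at known truth.
summaries_from_states <- function(screen_sim) {
  an <- screen_sim$animals
  pct <- t(vapply(an$data, function(s) percent_time(s)$pct, numeric(3)))
  tibble::tibble(
    gene = an$gene, role = an$role, animal_id = an$animal_id,
    pct_Q = pct[, 1], pct_D = pct[, 2], pct_R = pct[, 3]
  )
}
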