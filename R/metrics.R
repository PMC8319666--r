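# Accept either a decoded-states tibble (label [+ segment] columns) or a bare
# label vector; returns list(label = factor, segment = int, frame_rate_hz).
normalize_states_input <- function(states, frame_rate_hz = NULL) {
  if (is.data.frame(states)) {
    stopifnot("label" %in% names(states))
    lab <- as_state_factor(states$label)
    seg <- if ("segment" %in% names(states)) as.integer(states$segment)
           else rep(1L, nrow(states))
    if (is.null(frame_rate_hz)) {
      frame_rate_hz <- if ("time_s" %in% names(states) && nrow(states) > 1) {
        dt <- stats::median(diff(states$time_s))
        if (is.finite(dt) && dt > 0) 1 / dt else 1
      } else 1
    }
    list(label = lab, segment = seg, frame_rate_hz = frame_rate_hz)
  } else {
    list(label = as_state_factor(states),
         segment = rep(1L, length(states)),
         frame_rate_hz = frame_rate_hz %||% 1)
  }
}

#' Percent time in each behavioral state
#'
#' Frame counts per state divided by total labeled frames, reported both as
#' fractions and percentages. Fractions sum to 1 exactly.
#'
#' @param states Decoded states (a [decode_states()] tibble) or a label
#'   vector/factor with levels `Q`, `D`, `R`.
#' @return Tibble: `state`, `n_frames`, `frac`, `pct`.
#' @export
#' @examples
#' percent_time(rep(c("Q", "D"), c(900, 900)))
percent_time <- function(states) {
  s <- normalize_states_input(states)
  n <- length(s$label)
  if (n == 0) stop("no labeled frames", call. = FALSE)
  counts <- tabulate(as.integer(s$label), nbins = 3)
  tibble(
    state = factor(STATES, levels = STATES),
    n_frames = counts,
    frac = counts / n,
    pct = 100 * counts / n
  )
}

#' Estimate per-second transition rates from decoded states
#'
#' The estimator is the maximum-likelihood rate of the embedded discrete
#' chain: `rate[i -> j] = n(i -> j) / occupancy_s(i)`, where `n(i -> j)`
#' counts decoded i-to-j steps between consecutive frames within a segment,
#' and occupancy time counts only frames of state `i` that have a decoded
#' successor (so the denominator is exactly the number of opportunities to
#' leave). Segments split by tracking gaps contribute independently; no
#' transition is counted across a gap. Rates are per second, the analog of a
#' first-order rate constant. Diagonal entries are reported as 0 with
#' `is_self = TRUE`; rates out of a never-occupied state are `NA`.
#'
#' @inheritParams percent_time
#' @param frame_rate_hz Frames per second; inferred from `time_s` when the
#'   input is a decoded tibble, else defaults to 1.
#' @return Tibble: `from`, `to`, `n_transitions`, `occupancy_s`,
#'   `rate_per_s`, `is_self`.
#' @export
#' @examples
#' transition_rates(c("D", "D", "Q", "Q", "Q", "D"), frame_rate_hz = 1)
transition_rates <- function(states, frame_rate_hz = NULL) {
  s <- normalize_states_input(states, frame_rate_hz)
  lab <- as.integer(s$label)
  if (length(lab) < 2) stop("need at least 2 contiguous labeled frames", call. = FALSE)
  same_seg <- s$segment[-1] == s$segment[-length(lab)]
  from <- lab[-length(lab)][same_seg]
  to <- lab[-1][same_seg]
  counts <- matrix(tabulate(from + (to - 1L) * 3L, nbins = 9L), 3, 3)
  occ_frames <- tabulate(from, nbins = 3)
  occ_s <- occ_frames / s$frame_rate_hz
  grid <- expand.grid(from = 1:3, to = 1:3)
  rate <- ifelse(occ_s[grid$from] > 0, counts[cbind(grid$from, grid$to)] / occ_s[grid$from],
                 NA_real_)
  rate[grid$from == grid$to & !is.na(rate)] <- 0
  out <- tibble(
    from = factor(STATES[grid$from], levels = STATES),
    to = factor(STATES[grid$to], levels = STATES),
    n_transitions = counts[cbind(grid$from, grid$to)],
    occupancy_s = occ_s[grid$from],
    rate_per_s = rate,
    is_self = grid$from == grid$to
  )
  dplyr::arrange(out, .data$from, .data$to)
}

#' Bout durations per behavioral state
#'
#' A bout is a maximal run of consecutive frames in one state within a
#' segment; its duration is the run length over the frame rate. Bouts
#' truncated by the start/end of a segment (recording edges or tracking gaps)
#' are flagged censored: their true duration is unknown.
#'
#' @inheritParams transition_rates
#' @return Tibble: `segment`, `state`, `start_index`, `n_frames`,
#'   `duration_s`, `censored_left`, `censored_right`, `censored`.
#' @export
#' @examples
#' bout_durations(rep(c("Q", "D"), 5), frame_rate_hz = 1)
bout_durations <- function(states, frame_rate_hz = NULL) {
  s <- normalize_states_input(states, frame_rate_hz)
  if (length(s$label) == 0) {
    return(tibble(segment = integer(), state = factor(character(), levels = STATES),
                  start_index = integer(), n_frames = integer(),
                  duration_s = numeric(), censored_left = logical(),
                  censored_right = logical(), censored = logical()))
  }
  purrr::map_dfr(split(seq_along(s$label), s$segment), function(ii) {
    r <- rle(as.integer(s$label[ii]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nb <- length(r$lengths)
    tibble(
      segment = s$segment[ii[1]],
      state = factor(STATES[r$values], levels = STATES),
      start_index = ii[starts],
      n_frames = r$lengths,
      duration_s = r$lengths / s$frame_rate_hz,
      censored_left = seq_len(nb) == 1L,
      censored_right = seq_len(nb) == nb,
      censored = seq_len(nb) == 1L | seq_len(nb) == nb
    )
  })
}

#' Per-animal behavior summary
#'
#' One row per animal: percent time in roaming/dwelling/quiescence and the six
#' off-diagonal transition rates in wide format (`rate_QD` = quiescence to
#' dwelling, etc.), the per-animal readouts of the satiety-quiescence assay.
#'
#' @param decoded A [decode_states()] tibble, possibly covering several
#'   animals (`animal_id` column), or any tibble with `animal_id`, `label`
#'   and optionally `segment`/`time_s`.
#' @param frame_rate_hz Frames per second (inferred from `time_s` if absent).
#' @return Tibble with columns `animal_id`, `n_valid_frames`, `pct_R`,
#'   `pct_D`, `pct_Q`, `rate_QD`, `rate_QR`, `rate_DQ`, `rate_DR`,
#'   `rate_RQ`, `rate_RD` (s^-1).
#' @export
behavior_summary <- function(decoded, frame_rate_hz = NULL) {
  stopifnot(is.data.frame(decoded), "label" %in% names(decoded))
  if (!"animal_id" %in% names(decoded)) decoded$animal_id <- "worm"
  purrr::map_dfr(split(decoded, decoded$animal_id), function(d) {
    pt <- percent_time(d)
    tr <- transition_rates(d, frame_rate_hz)
    tr <- tr[!tr$is_self, ]
    rates <- setNames(tr$rate_per_s, paste0("rate_", tr$from, tr$to))
    dplyr::bind_cols(
      tibble(animal_id = d$animal_id[1], n_valid_frames = nrow(d)),
      tibble(pct_R = pt$pct[pt$state == "R"],
             pct_D = pt$pct[pt$state == "D"],
             pct_Q = pt$pct[pt$state == "Q"]),
      as_tibble(as.list(rates[c("rate_QD", "rate_QR", "rate_DQ",
                                "rate_DR", "rate_RQ", "rate_RD")]))
    )
  })
}
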