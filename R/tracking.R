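#' Extract a worm centroid from a single grayscale frame
#'
#' Binarizes the frame (Otsu threshold by default), labels connected
#' components, keeps the largest component with area at least `min_area`
#' pixels, and returns its intensity-weighted centroid. Coordinates are
#' x = column, y = row, 0-based, origin top-left, pixel centers at integers.
#'
#' @param frame Numeric matrix (single-channel image), intensities in \[0, 1\].
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity cutoff when `threshold_method = "fixed"`.
#' @param min_area Minimum component area in pixels (default 5); pass 1 to
#'   accept point sources.
#' @return One-row tibble `x_px`, `y_px`, `area_px`, `valid`. When no
#'   component passes, `valid` is `FALSE` and the coordinates are `NA`.
#' @export
#' @examples
#' img <- matrix(0, 32, 32); img[21, 11] <- 1
#' extract_centroid(img, min_area = 1) # x = 10, y = 20
extract_centroid <- function(frame,
                             threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NULL,
                             min_area = 5) {
  threshold_method <- match.arg(threshold_method)
  if (!is.matrix(frame) || length(dim(frame)) != 2 || length(frame) == 0) {
    stop("frame must be a non-empty 2-D matrix", call. = FALSE)
  }
  miss <- tibble(x_px = NA_real_, y_px = NA_real_, area_px = 0L, valid = FALSE)
  rng <- range(frame)
  if (rng[1] == rng[2]) return(miss) # flat image: nothing to segment
  thr <- if (threshold_method == "otsu") {
    EBImage::otsu(frame, range = rng)
  } else {
    if (is.null(fixed_threshold)) stop("fixed_threshold required", call. = FALSE)
    fixed_threshold
  }
  bw <- frame > thr
  if (!any(bw)) return(miss)
  lab <- EBImage::bwlabel(bw * 1)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(miss)
  best <- keep[which.max(areas[keep])]
  sel <- lab == best
  wts <- frame * sel
  tot <- sum(wts)
  cols <- matrix(rep(seq_len(ncol(frame)) - 1, each = nrow(frame)), nrow(frame))
  rows <- matrix(rep(seq_len(nrow(frame)) - 1, times = ncol(frame)), nrow(frame))
  tibble(
    x_px = sum(wts * cols) / tot,
    y_px = sum(wts * rows) / tot,
    area_px = as.integer(areas[best]),
    valid = TRUE
  )
}

#' Build a centroid track from an image stack
#'
#' Runs [extract_centroid()] on every frame; frames with no detection are kept
#' but flagged invalid, so the time base stays uniform.
#'
#' @param frames List of grayscale matrices (see [read_frames()],
#'   [render_frames()]).
#' @param frame_rate_hz Frames per second (default 1).
#' @param animal_id Identifier stored with the track.
#' @param ... Passed to [extract_centroid()].
#' @return Track tibble: `animal_id`, `frame` (0-based), `time_s`, `x_px`,
#'   `y_px`, `valid`.
#' @export
build_track <- function(frames, frame_rate_hz = 1, animal_id = "worm", ...) {
  if (length(frames) < 2) stop("need at least 2 frames", call. = FALSE)
  cent <- purrr::map_dfr(frames, extract_centroid, ...)
  n <- length(frames)
  tibble(
    animal_id = animal_id,
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / frame_rate_hz,
    x_px = cent$x_px,
    y_px = cent$y_px,
    valid = cent$valid
  )
}

# centered moving average with shrinking windows at the edges
moving_average <- function(x, k) {
  if (k <= 1 || length(x) < 2) return(x)
  h <- k %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Compute a smoothed speed series from a centroid track
#'
#' Raw speed at each consecutive pair of valid frames is the Euclidean
#' centroid displacement divided by elapsed time; each sample is assigned to
#' the later frame of its pair. Runs of at most `max_gap_frames` invalid
#' frames are bridged by linear position interpolation (so the bridged speed
#' equals the gap-average speed and can never exceed the pre/post displacement
#' over the gap duration); longer dropouts split the series into independent
#' segments. An optional centered moving average of width `window_s` can then
#' be applied within each segment.
#'
#' Smoothing is off by default: the state model already accounts for the
#' centroid-noise floor through its quiescence emission component, and
#' averaging across state boundaries reshapes the per-state speed
#' distributions enough to hurt segmentation (it narrows the dwelling mode
#' and mixes quiescent frames upward). Use `window_s` only when raw centroid
#' noise is large relative to dwelling speeds.
#'
#' @param track Track tibble (`frame`, `time_s`, `x_px`, `y_px`, `valid`).
#' @param window_s Smoothing window length in seconds (default 0 = no
#'   smoothing).
#' @param max_gap_frames Longest invalid run to interpolate across (default 5).
#' @return Tibble: `animal_id`, `segment`, `frame`, `time_s`, `speed_px_s`
#'   (smoothed), `speed_raw_px_s`, `interpolated`. Empty (with a warning) if
#'   fewer than 2 valid frames.
#' @export
#' @examples
#' trk <- tibble::tibble(frame = 0:3, time_s = 0:3,
#'                       x_px = c(0, 3, 6, 9), y_px = c(0, 4, 8, 12),
#'                       valid = TRUE)
#' compute_speeds(trk, window_s = 0)$speed_px_s # 5 5 5
compute_speeds <- function(track, window_s = 0, max_gap_frames = 5) {
  stopifnot(all(c("frame", "time_s", "x_px", "y_px", "valid") %in% names(track)))
  animal <- if ("animal_id" %in% names(track)) track$animal_id[1] else "worm"
  idx <- which(track$valid)
  empty <- tibble(animal_id = character(), segment = integer(),
                  frame = integer(), time_s = numeric(),
                  speed_px_s = numeric(), speed_raw_px_s = numeric(),
                  interpolated = logical())
  if (length(idx) < 2) {
    warning("fewer than 2 valid frames; empty speed series", call. = FALSE)
    return(empty)
  }
  dt_frame <- stats::median(diff(track$time_s))
  frame_rate <- 1 / dt_frame
  gaps <- diff(track$frame[idx]) - 1L
  seg_break <- gaps > max_gap_frames
  seg_id <- cumsum(c(0L, as.integer(seg_break))) + 1L
  out <- purrr::map_dfr(split(seq_along(idx), seg_id), function(ii) {
    rows <- idx[ii]
    if (length(rows) < 2) return(NULL)
    f0 <- track$frame[rows[1]]; f1 <- track$frame[rows[length(rows)]]
    fr <- f0:f1
    tt <- track$time_s[rows[1]] + (fr - f0) * dt_frame
    xs <- stats::approx(track$frame[rows], track$x_px[rows], xout = fr)$y
    ys <- stats::approx(track$frame[rows], track$y_px[rows], xout = fr)$y
    interp <- !(fr %in% track$frame[rows])
    raw <- sqrt(diff(xs)^2 + diff(ys)^2) / diff(tt)
    k <- max(1L, 2L * (as.integer(round(window_s * frame_rate)) %/% 2L) + 1L)
    if (window_s <= 0) k <- 1L
    tibble(
      animal_id = animal,
      frame = fr[-1],
      time_s = tt[-1],
      speed_px_s = moving_average(raw, k),
      speed_raw_px_s = raw,
      interpolated = interp[-1]
    )
  }, .id = "segment")
  out$segment <- as.integer(out$segment)
  dplyr::relocate(out, "animal_id", "segment")
}
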