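TRACK_COLS <- c("frame", "time_s", "x_px", "y_px", "valid")
STATES_COLS <- c("frame", "time_s", "label", "p_Q", "p_D", "p_R")

check_monotone_time <- function(time_s, what) {
  bad <- which(diff(time_s) <= 0)
  if (length(bad) > 0) {
    stop(what, ": time_s not strictly increasing at row ", bad[1] + 1,
         call. = FALSE)
  }
}

#' Read and write centroid-track CSV files
#'
#' Tracks round-trip losslessly (full double precision); unknown columns are
#' preserved. The header must contain `frame,time_s,x_px,y_px,valid`;
#' synthetic tracks additionally carry `true_state`. Files with non-monotone
#' `time_s` are rejected with the offending row number.
#'
#' @param track Track tibble.
#' @param path File path.
#' @return `read_track_csv()` returns the track tibble; `write_track_csv()`
#'   returns `path` invisibly.
#' @export
write_track_csv <- function(track, path) {
  stopifnot(all(TRACK_COLS %in% names(track)))
  readr::write_csv(track, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  # base parser: strtod is correctly rounded, so written doubles come back
  # bit-for-bit (fast approximate float parsers can be 1 ulp off)
  x <- as_tibble(utils::read.csv(path))
  missing_cols <- setdiff(TRACK_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop("malformed track header in ", path, ": missing ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("animal_id" %in% names(x)) {
    for (a in split(x, x$animal_id)) check_monotone_time(a$time_s, path)
  } else {
    check_monotone_time(x$time_s, path)
  }
  x$valid <- as.logical(x$valid)
  if ("true_state" %in% names(x)) x$true_state <- as_state_factor(x$true_state)
  x
}

#' Read and write decoded-state CSV files
#'
#' @param states A [decode_states()] tibble.
#' @param path File path.
#' @return The states tibble (read) or `path` invisibly (write).
#' @export
write_states_csv <- function(states, path) {
  stopifnot(all(STATES_COLS %in% names(states)))
  readr::write_csv(states, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_states_csv
#' @export
read_states_csv <- function(path) {
  x <- as_tibble(utils::read.csv(path)) # see read_track_csv on precision
  missing_cols <- setdiff(STATES_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop("malformed states header in ", path, ": missing ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$label <- as_state_factor(x$label)
  class(x) <- c("quiescr_states", class(x))
  x
}

#' Serialize HMM parameters as JSON
#'
#' Full double precision; a write-read round trip reproduces the transition
#' matrix elementwise.
#'
#' @param params A `quiescr_hmm`.
#' @param path File path.
#' @return The model (read) or `path` invisibly (write).
#' @export
write_hmm_json <- function(params, path) {
  validate_hmm(params)
  payload <- list(
    pi = params$pi, A = params$A, mu = params$mu, sigma = params$sigma,
    epsilon = params$epsilon, states = params$states,
    logLik = params$logLik, n_iter = params$n_iter,
    converged = params$converged
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- hmm_params(x$pi, x$A, x$mu, x$sigma, epsilon = x$epsilon)
  p$logLik <- x$logLik %||% NA_real_
  p$n_iter <- x$n_iter %||% NA_integer_
  p$converged <- x$converged %||% NA
  p
}

#' Write an image stack as multi-page TIFF
#'
#' Lossless 16-bit output (intensities clipped to \[0, 1\]).
#'
#' @param frames List of grayscale matrices.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  frames <- lapply(frames, function(f) {
    f[f < 0] <- 0; f[f > 1] <- 1; f
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an image stack
#'
#' Accepts a single multi-page TIFF path or a character vector of PNG/TIFF
#' frame paths (sorted order is the caller's responsibility). Color images
#' are collapsed to grayscale by channel averaging.
#'
#' @param paths One TIFF path or a vector of frame paths.
#' @return List of grayscale matrices.
#' @export
read_frames <- function(paths) {
  to_gray <- function(img) {
    if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE],
                                            c(1, 2), mean)
    img
  }
  if (length(paths) == 1 && grepl("\\.tiff?$", paths, ignore.case = TRUE)) {
    frames <- tiff::readTIFF(paths, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    return(lapply(frames, to_gray))
  }
  lapply(paths, function(p) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) to_gray(png::readPNG(p))
    else to_gray(tiff::readTIFF(p))
  })
}
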