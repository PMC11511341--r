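#' The 14-landmark planar schema
#'
#' Canonical landmark identifiers: `<side>_<name>` with side `left`/`right`
#' and name one of `shoulder`, `hip`, `knee`, `ankle`, `heel`, `small_toe`,
#' `big_toe`. Coordinates are planar: X posterior--anterior, Z vertical (up),
#' both in meters; the mediolateral axis is discarded at read time.
#'
#' @format Character vectors.
#' @name landmark_schema
NULL

.landmark_names <- c("shoulder", "hip", "knee", "ankle", "heel",
                     "small_toe", "big_toe")
.sides <- c("left", "right")

#' All canonical landmark identifiers
#'
#' @return Character vector of the 14 `<side>_<name>` landmark ids.
#' @export
#' @examples
#' landmark_ids()
landmark_ids <- function() {
  as.vector(t(outer(.sides, .landmark_names, paste, sep = "_")))
}

side_landmarks <- function(side) paste(side, .landmark_names, sep = "_")

#' Construct a landmark trajectory set
#'
#' Container for time-stamped planar coordinates of body landmarks sampled at
#' a fixed rate. Each landmark is an `n x 2` matrix with columns `x` and `z`
#' (meters). All series must share one length (at least 2 samples). Missing
#' samples (pre gap-filling) are `NA` in both columns.
#'
#' @param landmarks Named list of `n x 2` numeric matrices (columns `x`, `z`),
#'   names from [landmark_ids()].
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param t0_s Time of the first sample in seconds.
#' @param source_label Free-text provenance label, e.g. `"marker"` or
#'   `"markerless"`.
#' @param side Which side must be complete: `"any"` (default; at least one
#'   complete side required), `"left"`, `"right"`, or `"both"`.
#' @return An object of class `landmark_set` with fields `landmarks`,
#'   `sampling_rate_hz`, `t0_s`, `source_label`, `recording_side`.
#' @export
landmark_set <- function(landmarks, sampling_rate_hz, t0_s = 0,
                         source_label = "unknown", side = "any") {
  if (!is.list(landmarks) || is.null(names(landmarks)) ||
      any(!nzchar(names(landmarks))))
    stop("`landmarks` must be a named list of n x 2 matrices", call. = FALSE)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be a single positive number", call. = FALSE)
  landmarks <- lapply(landmarks, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("each landmark series must have 2 columns (x, z)",
                           call. = FALSE)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "z")
    m
  })
  lens <- vapply(landmarks, nrow, integer(1))
  if (length(unique(lens)) != 1)
    stop("all landmark series must have identical length", call. = FALSE)
  if (lens[[1]] < 2)
    stop("landmark series must have length >= 2", call. = FALSE)

  complete <- vapply(.sides, function(s) {
    all(side_landmarks(s) %in% names(landmarks))
  }, logical(1))
  recording_side <- if (all(complete)) "both"
    else if (complete[["left"]]) "left"
    else if (complete[["right"]]) "right"
    else "none"
  req_sides <- switch(side,
    any   = NULL,
    both  = .sides,
    left  = "left",
    right = "right",
    stop("`side` must be one of 'any', 'left', 'right', 'both'", call. = FALSE))
  if (is.null(req_sides)) {
    if (recording_side == "none") {
      missing_by_side <- lapply(.sides, function(s)
        setdiff(side_landmarks(s), names(landmarks)))
      stop("no complete landmark side; missing: ",
           paste(unlist(missing_by_side), collapse = ", "), call. = FALSE)
    }
  } else {
    miss <- unlist(lapply(req_sides, function(s)
      setdiff(side_landmarks(s), names(landmarks))))
    if (length(miss))
      stop("missing required landmarks: ",
           paste(sub("_", " ", miss), collapse = ", "), call. = FALSE)
  }

  structure(list(
    landmarks = landmarks,
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    t0_s = as.numeric(t0_s),
    source_label = as.character(source_label),
    recording_side = recording_side
  ), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  n <- nrow(x$landmarks[[1]])
  cat(sprintf(
    "<landmark_set> %d landmarks, %d samples @ %g Hz (%.2f s), side: %s, source: %s\n",
    length(x$landmarks), n, x$sampling_rate_hz, n / x$sampling_rate_hz,
    x$recording_side, x$source_label))
  nmiss <- sum(vapply(x$landmarks, function(m) sum(!stats::complete.cases(m)),
                      integer(1)))
  if (nmiss > 0) cat(sprintf("  %d landmark-samples flagged missing\n", nmiss))
  invisible(x)
}

#' Time stamps of a landmark set
#'
#' @param tset A [landmark_set()].
#' @return Numeric vector of sample times in seconds.
#' @export
time_of <- function(tset) {
  stopifnot(inherits(tset, "landmark_set"))
  n <- nrow(tset$landmarks[[1]])
  tset$t0_s + (seq_len(n) - 1) / tset$sampling_rate_hz
}

n_samples <- function(tset) nrow(tset$landmarks[[1]])

#' Extract one coordinate series of one landmark
#'
#' @param tset A [landmark_set()].
#' @param landmark Landmark id, e.g. `"left_big_toe"`.
#' @param coord `"z"` (default) or `"x"`.
#' @return Numeric vector.
#' @export
landmark_series <- function(tset, landmark, coord = "z") {
  stopifnot(inherits(tset, "landmark_set"))
  if (!landmark %in% names(tset$landmarks))
    stop("landmark not present: ", landmark, call. = FALSE)
  coord <- match.arg(coord, c("z", "x"))
  tset$landmarks[[landmark]][, coord]
}
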