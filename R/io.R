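#' Read a landmark trajectory TSV
#'
#' Two dialects are supported. The `"internal"` dialect is normative for this
#' package: key-value header lines (tab-separated) of which `FREQUENCY` (Hz)
#' and `MARKER_NAMES` are required (`T0`, `SOURCE`, `SIDE`, `UNITS` optional),
#' followed by a column-header row `<name>_X <name>_Z ...` and one data row
#' per sample, coordinates in meters unless `UNITS mm` is declared. The
#' `"qualisys"` dialect is a reader shim for the common motion-capture export:
#' key-value header lines up to `MARKER_NAMES` (and optional
#' `TRAJECTORY_TYPES`), then rows of X Y Z triplets per marker in millimetres;
#' the mediolateral Y column is discarded.
#'
#' Landmark names are lower-cased and matched against the canonical schema
#' after applying `aliases`; unknown columns are dropped with a warning.
#'
#' @param path Path to a TSV file.
#' @param dialect `"internal"` (default) or `"qualisys"`.
#' @param units Coordinate units: `"auto"` (header-declared, defaulting to m
#'   for internal and mm for qualisys), `"m"`, or `"mm"`.
#' @param aliases Named character vector mapping file landmark names to
#'   canonical ids (names = file names, values = canonical), or `NULL`.
#' @param side Passed to [landmark_set()]: which side must be complete.
#' @param source_label Override for the provenance label (default: header
#'   `SOURCE` value or the dialect name).
#' @return A [landmark_set()].
#' @export
read_trajectories <- function(path, dialect = c("internal", "qualisys"),
                              units = "auto", aliases = NULL, side = "any",
                              source_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)

  header <- list()
  i <- 1
  header_keys <- c("FREQUENCY", "MARKER_NAMES", "T0", "SOURCE", "SIDE",
                   "UNITS", "NO_OF_FRAMES", "NO_OF_CAMERAS", "NO_OF_MARKERS",
                   "NO_OF_ANALOG", "ANALOG_FREQUENCY", "DESCRIPTION",
                   "TIME_STAMP", "DATA_INCLUDED", "TRAJECTORY_TYPES", "EVENT")
  while (i <= length(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    key <- toupper(trimws(fields[1]))
    if (!key %in% header_keys) break
    header[[key]] <- trimws(fields[-1])
    i <- i + 1
  }
  if (is.null(header$FREQUENCY))
    stop("header missing FREQUENCY line", call. = FALSE)
  fs <- suppressWarnings(as.numeric(header$FREQUENCY[1]))
  if (!is.finite(fs) || fs <= 0)
    stop("invalid FREQUENCY: ", header$FREQUENCY[1], call. = FALSE)
  if (is.null(header$MARKER_NAMES))
    stop("header missing MARKER_NAMES line", call. = FALSE)
  raw_names <- header$MARKER_NAMES
  raw_names <- raw_names[nzchar(raw_names)]

  canon <- tolower(raw_names)
  if (!is.null(aliases)) {
    hit <- match(tolower(canon), tolower(names(aliases)))
    canon[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  canon <- tolower(canon)
  known <- canon %in% landmark_ids()
  if (any(!known))
    warning("ignoring unknown landmark column(s): ",
            paste(raw_names[!known], collapse = ", "), call. = FALSE)

  data_lines <- lines[i:length(lines)]
  # internal dialect carries its own column-header row
  if (dialect == "internal" && length(data_lines) &&
      grepl("_[XZ]", data_lines[1], ignore.case = TRUE) &&
      is.na(suppressWarnings(as.numeric(strsplit(data_lines[1], "\t")[[1]][1]))))
    data_lines <- data_lines[-1]
  if (!length(data_lines)) stop("no data rows in ", path, call. = FALSE)

  rows <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_per <- if (dialect == "internal") 2L else 3L
  expected <- length(raw_names) * ncol_per
  mat <- matrix(NA_real_, nrow = length(rows), ncol = expected)
  for (r in seq_along(rows)) {
    fields <- trimws(rows[[r]])
    fields <- fields[seq_len(min(length(fields), expected))]
    vals <- suppressWarnings(as.numeric(fields))
    bad <- which(is.na(vals) & nzchar(fields) & !toupper(fields) %in%
                   c("NA", "NAN", "NULL"))
    if (length(bad))
      stop(sprintf("non-numeric cell in data row %d (column %d): '%s'",
                   r, bad[1], fields[bad[1]]), call. = FALSE)
    mat[r, seq_along(vals)] <- vals
  }

  unit <- if (identical(units, "auto")) {
    if (!is.null(header$UNITS)) tolower(header$UNITS[1])
    else if (dialect == "qualisys") "mm" else "m"
  } else match.arg(units, c("m", "mm"))
  scale <- if (unit == "mm") 1e-3 else 1

  landmarks <- list()
  for (j in which(known)) {
    base <- (j - 1) * ncol_per
    x <- mat[, base + 1] * scale
    z <- mat[, base + ncol_per] * scale   # col 2 (internal) or col 3 (qualisys)
    if (dialect == "qualisys") {
      # exports flag missing samples as exact zeros in all three coordinates
      zero <- mat[, base + 1] == 0 & mat[, base + 2] == 0 & mat[, base + 3] == 0
      x[zero] <- NA_real_; z[zero] <- NA_real_
    }
    landmarks[[canon[j]]] <- cbind(x = x, z = z)
  }
  if (!length(landmarks)) stop("no recognised landmark columns in ", path,
                               call. = FALSE)

  t0 <- if (!is.null(header$T0))
    suppressWarnings(as.numeric(header$T0[1])) else 0
  if (!is.finite(t0)) t0 <- 0
  src <- if (!is.null(source_label)) source_label
    else if (!is.null(header$SOURCE)) header$SOURCE[1] else dialect
  landmark_set(landmarks, sampling_rate_hz = fs, t0_s = t0,
               source_label = src, side = side)
}

#' Write a landmark trajectory TSV (internal dialect)
#'
#' Writes the documented internal dialect: `FREQUENCY`, `T0`, `SOURCE`,
#' `SIDE`, `UNITS m`, `MARKER_NAMES` header lines, a `<name>_X <name>_Z`
#' column-header row, then one row per sample, landmark-major.
#'
#' @param tset A [landmark_set()].
#' @param path Output path.
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tset, path, digits = 10) {
  stopifnot(inherits(tset, "landmark_set"))
  if (!length(tset$landmarks)) stop("empty landmark map", call. = FALSE)
  nm <- names(tset$landmarks)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  writeLines(c(
    paste0("FREQUENCY\t", fmt(tset$sampling_rate_hz)),
    paste0("T0\t", fmt(tset$t0_s)),
    paste0("SOURCE\t", tset$source_label),
    paste0("SIDE\t", tset$recording_side),
    "UNITS\tm",
    paste(c("MARKER_NAMES", nm), collapse = "\t"),
    paste(as.vector(rbind(paste0(nm, "_X"), paste0(nm, "_Z"))),
          collapse = "\t")
  ), con)
  block <- do.call(cbind, lapply(tset$landmarks, function(m) m[, c("x", "z")]))
  utils::write.table(
    matrix(fmt(block), nrow = nrow(block)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    na = "NA")
  invisible(path)
}

#' Fill short interior gaps in a coordinate series
#'
#' Missing samples are `NA`. Interior runs of at most `max_gap` missing
#' samples are filled by linear interpolation over the flanking present
#' samples, or by a local polynomial (default cubic) fitted to up to `flank`
#' present samples on each side of the gap. Present samples are never
#' modified; gaps longer than `max_gap`, or leading/trailing gaps, raise an
#' error.
#'
#' @param series Numeric vector with `NA` for missing samples.
#' @param method `"linear"` or `"polynomial"`.
#' @param max_gap Maximum fillable gap length in samples.
#' @param order Polynomial order for `method = "polynomial"` (default 3).
#' @param flank Present samples used on each side of a gap for the
#'   polynomial fit (default 5).
#' @return The series with gaps filled.
#' @export
gap_fill <- function(series, method = c("linear", "polynomial"),
                     max_gap = 10, order = 3, flank = 5) {
  method <- match.arg(method)
  x <- as.numeric(series)
  n <- length(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (miss[1] || miss[n])
    stop("leading/trailing gap cannot be filled", call. = FALSE)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    g0 <- starts[k]; g1 <- ends[k]
    if (r$lengths[k] > max_gap)
      stop(sprintf("gap of %d samples at [%d, %d] exceeds max_gap = %d",
                   r$lengths[k], g0, g1, max_gap), call. = FALSE)
    idx <- g0:g1
    if (method == "linear") {
      x[idx] <- stats::approx(c(g0 - 1, g1 + 1), x[c(g0 - 1, g1 + 1)],
                              xout = idx)$y
    } else {
      left <- max(1, g0 - flank):(g0 - 1)
      right <- (g1 + 1):min(n, g1 + flank)
      sup <- c(left, right)
      sup <- sup[!is.na(x[sup])]
      deg <- min(order, length(sup) - 1)
      fit <- stats::lm(y ~ poly(t, deg, raw = TRUE),
                       data = data.frame(t = sup, y = x[sup]))
      x[idx] <- stats::predict(fit, newdata = data.frame(t = idx))
    }
  }
  x
}

#' Gap-fill every landmark of a set
#'
#' @inheritParams gap_fill
#' @param tset A [landmark_set()].
#' @param max_gap_s Maximum fillable gap in seconds (default 0.1 s).
#' @return A [landmark_set()] with finite coordinates.
#' @export
gap_fill_set <- function(tset, method = "linear", max_gap_s = 0.1,
                         order = 3, flank = 5) {
  stopifnot(inherits(tset, "landmark_set"))
  max_gap <- max(1L, floor(max_gap_s * tset$sampling_rate_hz))
  tset$landmarks <- lapply(tset$landmarks, function(m) {
    cbind(x = gap_fill(m[, "x"], method, max_gap, order, flank),
          z = gap_fill(m[, "z"], method, max_gap, order, flank))
  })
  tset
}

#' Resample a landmark set onto a uniform grid
#'
#' Every coordinate series is linearly interpolated onto a uniform grid at
#' `target_hz` spanning the original time range.
#'
#' @param tset A [landmark_set()].
#' @param target_hz Target sampling rate in Hz.
#' @return A [landmark_set()] at the new rate.
#' @export
resample_trajectories <- function(tset, target_hz) {
  stopifnot(inherits(tset, "landmark_set"))
  if (!is.numeric(target_hz) || target_hz <= 0)
    stop("`target_hz` must be positive", call. = FALSE)
  t_old <- time_of(tset)
  dur <- t_old[length(t_old)] - t_old[1]
  n_new <- floor(dur * target_hz + 1e-9) + 1
  if (n_new < 2) stop("target grid would have < 2 samples", call. = FALSE)
  t_new <- tset$t0_s + (seq_len(n_new) - 1) / target_hz
  tset$landmarks <- lapply(tset$landmarks, function(m) {
    cbind(x = stats::approx(t_old, m[, "x"], xout = t_new)$y,
          z = stats::approx(t_old, m[, "z"], xout = t_new)$y)
  })
  tset$sampling_rate_hz <- as.numeric(target_hz)
  tset
}

#' Residual temporal offset between two CoM trajectories
#'
#' Maximises the normalised cross-correlation of the vertical CoM series over
#' integer lags within `max_lag_s`. Ties are broken toward the smallest
#' absolute lag, then the negative lag. A positive lag means `b` starts later
#' than `a`.
#'
#' @param a,b [com_trajectory] objects at the same sampling rate.
#' @param max_lag_s Search half-window in seconds.
#' @return Lag in seconds.
#' @export
align_pair <- function(a, b, max_lag_s = 0.5) {
  stopifnot(inherits(a, "com_trajectory"), inherits(b, "com_trajectory"))
  if (abs(a$sampling_rate_hz - b$sampling_rate_hz) > 1e-9)
    stop("trajectories must share one sampling rate", call. = FALSE)
  fs <- a$sampling_rate_hz
  za <- a$com_z_m - mean(a$com_z_m)
  zb <- b$com_z_m - mean(b$com_z_m)
  max_lag <- floor(max_lag_s * fs)
  if (min(length(za), length(zb)) <= 2 * max_lag)
    stop("series shorter than twice the maximum lag", call. = FALSE)
  lags <- -max_lag:max_lag
  score <- vapply(lags, function(L) {
    ia <- seq_along(za); ib <- ia + L
    ok <- ib >= 1 & ib <= length(zb)
    mean(za[ia[ok]] * zb[ib[ok]])
  }, numeric(1))
  best <- score >= max(score) - 1e-12
  cand <- lags[best]
  cand <- cand[order(abs(cand), cand)]
  cand[1] / fs
}

#' Read a YAML run configuration
#'
#' Recognised blocks: `aliases` (file-name to canonical landmark map),
#' `units`, `dialect`, `detection` (passed to [cmj_config()]), `smoothing`
#' (`window_s`, `alpha`), `resample_hz`, `n_stations`, `aggregation`, `seed`.
#' Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  if (!is.null(cfg$aliases)) cfg$aliases <- unlist(cfg$aliases)
  cfg
}
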