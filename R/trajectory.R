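#' Read trajectory point tracks from CSV
#'
#' Reads a point-export table (one tracked position per row) of the kind
#' produced by interactive trackers such as MTrackJ, after an optional
#' column mapping. Points within each track are ordered by time.
#'
#' @param path CSV path with header `track_id,t,x,y` (or mapped names).
#' @param col_map Optional named character vector mapping canonical names
#'   (`track_id`, `t`, `x`, `y`) to the file's headers.
#' @return Tibble with columns `track_id`, `t`, `x`, `y`, sorted by
#'   track and time.
#' @export
read_tracks <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  wanted <- c("track_id", "t", "x", "y")
  map <- stats::setNames(wanted, wanted)
  if (!is.null(col_map)) map[names(col_map)] <- unname(col_map)
  missing <- map[!map %in% names(raw)]
  if (length(missing) > 0)
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  out <- tibble::as_tibble(stats::setNames(raw[unname(map)], wanted))
  out$track_id <- as.character(out$track_id)
  dplyr::arrange(out, .data$track_id, .data$t)
}

#' Instantaneous step speeds of a track
#'
#' The speed over each step between consecutive tracked points: Euclidean
#' displacement divided by the elapsed time. Missing frames simply
#' lengthen the time gap of the affected step; no interpolation or
#' smoothing is applied. Units follow the input (length units per second
#' when `t` is in seconds).
#'
#' @param track Data frame with numeric columns `t`, `x`, `y` for a single
#'   track, ordered (or orderable) by `t`.
#' @return Numeric vector of length `nrow(track) - 1`.
#' @export
step_speeds <- function(track) {
  if (nrow(track) < 2) stop("a track needs at least 2 points for a speed")
  o <- order(track$t)
  t <- track$t[o]; x <- track$x[o]; y <- track$y[o]
  dt <- diff(t)
  dup <- which(dt <= 0)
  if (length(dup) > 0)
    stop("duplicate or non-increasing timestamps at points ",
         dup[1], " and ", dup[1] + 1L, " (t = ", t[dup[1]], ")")
  sqrt(diff(x)^2 + diff(y)^2) / dt
}

#' Velocity summary of a track
#'
#' The three behavioral phenotypes derived from a trajectory: maximum step
#' speed, mean step speed, and the sample standard deviation (n-1) of step
#' speeds, the last quantifying how erratic the movement is.
#'
#' @param track Data frame with columns `t`, `x`, `y` for one track.
#' @param permissive Allow tracks with exactly 2 points (one step); the
#'   SD is then reported as `NA` with a warning. Default `FALSE`.
#' @return Tibble with one row: `max_velocity`, `mean_velocity`,
#'   `sd_velocity`, `n_steps`.
#' @export
velocity_summary <- function(track, permissive = FALSE) {
  if (nrow(track) < 3) {
    if (!(permissive && nrow(track) == 2))
      stop("a track needs at least 3 points (2 steps) for a velocity summary")
    warning("track has a single step: sd_velocity is undefined")
  }
  v <- step_speeds(track)
  tibble::tibble(
    max_velocity = max(v),
    mean_velocity = mean(v),
    sd_velocity = if (length(v) >= 2) stats::sd(v) else NA_real_,
    n_steps = length(v)
  )
}

#' Velocity phenotypes for a table of tracks
#'
#' Applies [velocity_summary()] to each track of a multi-track point
#' table, yielding the per-individual behavioral traits.
#'
#' @param tracks Tibble from [read_tracks()] or [simulate_tracks()].
#' @inheritParams velocity_summary
#' @return Tibble with one row per `track_id`.
#' @export
track_phenotypes <- function(tracks, permissive = FALSE) {
  tracks |>
    dplyr::group_by(track_id = .data$track_id) |>
    dplyr::group_modify(~ velocity_summary(.x, permissive = permissive)) |>
    dplyr::ungroup()
}
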