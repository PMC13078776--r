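# Track table I/O: the trajectory CSV schema
# (track_id,frame,time_s,x_um,y_um), a TrackMate spots-export converter,
# and the end-to-end analysis driver.

#' Write a track table to CSV
#'
#' Columns `track_id,frame,time_s,x_um,y_um`, UTF-8, '.' decimal.
#'
#' @param tracks A track table.
#' @param path Output file.
#' @return `tracks`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  validate_tracks(tracks)
  out <- tracks
  if (!"frame" %in% names(out)) {
    out <- out |>
      dplyr::group_by(.data$track_id) |>
      dplyr::mutate(frame = dplyr::row_number() - 1L) |>
      dplyr::ungroup()
  }
  readr::write_csv(out[, c("track_id", "frame", "time_s", "x_um", "y_um")],
                   path)
  invisible(tracks)
}

#' Read a track table from CSV
#'
#' @param path CSV file in the trajectory schema
#'   (`track_id,frame,time_s,x_um,y_um`, header required).
#' @return A track tibble.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_bad_input(paste0("read_tracks: no such file: ", path))
  tr <- try(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
            silent = TRUE)
  if (inherits(tr, "try-error") || nrow(tr) == 0)
    stop_bad_input(paste0("read_tracks: cannot parse ", path))
  validate_tracks(tr)
  # file order is preserved so written fixtures round-trip identically
  dplyr::mutate(tr, track_id = as.character(.data$track_id))
}

#' Convert a TrackMate spots export to the track schema
#'
#' Reads the spots CSV written by TrackMate (columns `TRACK_ID`, `FRAME`,
#' `POSITION_X`, `POSITION_Y`, and optionally `POSITION_T`), skipping the
#' extra non-numeric header rows of newer exports, and returns a track
#' table. Spots without a track assignment are dropped.
#'
#' @param path TrackMate spots CSV.
#' @param frame_interval Frame interval (s) used when `POSITION_T` is
#'   absent or not numeric.
#' @param pixel_size Multiplier applied to positions (um per position unit;
#'   1 when TrackMate already exported calibrated um).
#' @return A track tibble.
#' @export
read_trackmate <- function(path, frame_interval = 0.05, pixel_size = 1) {
  if (!file.exists(path)) stop_bad_input(paste0("read_trackmate: no such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% names(raw)))
    stop_bad_input(paste0("read_trackmate: expected columns ",
                          paste(need, collapse = ", ")))
  num <- function(v) suppressWarnings(as.numeric(as.character(v)))
  df <- tibble(
    track_id = as.character(raw$TRACK_ID),
    frame = num(raw$FRAME),
    x_um = num(raw$POSITION_X) * pixel_size,
    y_um = num(raw$POSITION_Y) * pixel_size,
    time_s = if ("POSITION_T" %in% names(raw)) num(raw$POSITION_T)
             else num(raw$FRAME) * frame_interval
  )
  df <- df[!is.na(df$frame) & !is.na(df$x_um) & !is.na(df$y_um) &
             !is.na(df$track_id) & df$track_id != "None", ]
  if (any(is.na(df$time_s))) df$time_s <- df$frame * frame_interval
  df |>
    dplyr::mutate(frame = as.integer(.data$frame)) |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::select("track_id", "frame", "time_s", "x_um", "y_um")
}

#' End-to-end trajectory analysis
#'
#' Drives the full statistics suite on a track table: ensemble and
#' per-region drift, region proportions, the RSW up/down-gradient split,
#' per-track speed and rotational exponent, and tumble events per track.
#'
#' @param tracks A track table (simulated or from tracking software).
#' @param lane_width Lane width (um).
#' @param d Wall threshold (um).
#' @param min_frames Tracks with fewer frames are dropped (velocity needs 5;
#'   the default keeps the drift estimator well fed).
#' @return An object of class `lane_analysis`: `$summary` (one row),
#'   `$drift` (ensemble [drift_velocity()]), `$region_drift`,
#'   `$regions`, `$rsw_split`, `$per_track`.
#' @export
analyze_tracks <- function(tracks, lane_width, d = 3, min_frames = 5) {
  validate_tracks(tracks)
  keep <- tracks |>
    dplyr::count(.data$track_id) |>
    dplyr::filter(.data$n >= min_frames)
  tracks <- dplyr::semi_join(tracks, keep, by = "track_id")
  if (nrow(tracks) == 0) stop_bad_input("analyze_tracks: no usable tracks")
  cls <- classify_region(tracks, lane_width, d)
  drift <- drift_velocity(tracks)
  region_drift <- cls |>
    dplyr::group_split(.data$region) |>
    purrr::map(function(g) {
      sub <- dplyr::semi_join(tracks, g, by = "track_id")
      vd <- try(drift_velocity(sub), silent = TRUE)
      tibble(region = as.character(g$region[1]),
             n_tracks = nrow(g),
             v_d = if (inherits(vd, "try-error")) NA_real_ else vd$v_d,
             sd = if (inherits(vd, "try-error")) NA_real_ else vd$sd)
    }) |>
    dplyr::bind_rows()
  regions <- region_proportions(tracks, lane_width, d)
  rsw <- try(rsw_direction_split(tracks, lane_width, d), silent = TRUE)
  if (inherits(rsw, "try-error")) rsw <- NULL
  per_track <- dplyr::left_join(
    track_speed(tracks),
    track_rotational_exponents(tracks),
    by = "track_id"
  ) |>
    dplyr::left_join(cls[, c("track_id", "region")], by = "track_id")
  summary <- tibble(
    n_tracks = length(unique(tracks$track_id)),
    lane_width = lane_width,
    v_d = drift$v_d,
    v_d_sd = drift$sd,
    mean_speed = mean(per_track$speed),
    prop_lsw = regions$prop[regions$region == "LSW"],
    prop_ma = regions$prop[regions$region == "MA"],
    prop_rsw = regions$prop[regions$region == "RSW"],
    rsw_up = if (is.null(rsw)) NA_real_ else rsw$prop[rsw$direction == "up"]
  )
  structure(list(summary = summary, drift = drift,
                 region_drift = region_drift, regions = regions,
                 rsw_split = rsw, per_track = per_track,
                 lane_width = lane_width, d = d),
            class = "lane_analysis")
}

#' @export
print.lane_analysis <- function(x, ...) {
  cat(sprintf("Lane analysis: %d tracks, width %g um\n",
              x$summary$n_tracks, x$lane_width))
  cat(sprintf("  drift %.3f um/s; proportions LSW/MA/RSW = %.2f/%.2f/%.2f\n",
              x$summary$v_d, x$summary$prop_lsw, x$summary$prop_ma,
              x$summary$prop_rsw))
  invisible(x)
}

#' @export
glance.lane_analysis <- function(x, ...) x$summary

#' Write an analysis bundle to disk
#'
#' One CSV per statistic plus a JSON summary carrying a provenance block
#' (package version, parameters, timestamp) for reproducibility.
#'
#' @param analysis A `lane_analysis`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "lane_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(analysis$summary, file.path(dir, "summary.csv"))
  readr::write_csv(analysis$region_drift, file.path(dir, "region_drift.csv"))
  readr::write_csv(analysis$regions, file.path(dir, "region_proportions.csv"))
  readr::write_csv(analysis$per_track, file.path(dir, "per_track.csv"))
  if (!is.null(analysis$rsw_split))
    readr::write_csv(analysis$rsw_split, file.path(dir, "rsw_split.csv"))
  meta <- list(
    provenance = list(package = "lanetaxis",
                      version = as.character(packageVersion("lanetaxis")),
                      created = format(Sys.time(), tz = "UTC"),
                      lane_width = analysis$lane_width, d = analysis$d),
    summary = as.list(analysis$summary)
  )
  jsonlite::write_json(meta, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
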