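#' Read / write a fix file
#'
#' The fix CSV dialect has one row per recorded position:
#' `track_id, order, method, lon, lat, active`. `order` runs consecutively
#' from 0 within a track (0 = start/release point), `method` is `"DB"` or
#' `"GPS"`, coordinates are decimal degrees WGS84, `active` is logical.
#'
#' @param path File path.
#' @return `read_fixes()` returns a validated data.frame.
#' @export
read_fixes <- function(path) {
  fx <- read.csv(path, stringsAsFactors = FALSE)
  validate_fixes(fx)
  fx$active <- as.logical(fx$active)
  fx
}

#' @rdname read_fixes
#' @param fixes A fix data.frame as described above.
#' @export
write_fixes <- function(fixes, path) {
  validate_fixes(fixes)
  write.csv(fixes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_fixes <- function(fx) {
  need <- c("track_id", "order", "method", "lon", "lat", "active")
  miss <- setdiff(need, names(fx))
  if (length(miss))
    stop("fix table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!fx$method %in% c("DB", "GPS")))
    stop("method must be 'DB' or 'GPS'")
  if (any(fx$lon < -180 | fx$lon > 180 | fx$lat < -90 | fx$lat > 90))
    stop("coordinates outside WGS84 bounds")
  for (id in unique(fx$track_id)) {
    o <- sort(fx$order[fx$track_id == id])
    if (!identical(as.integer(o), seq_along(o) - 1L))
      stop(sprintf("track '%s': orders must be consecutive from 0", id))
  }
  invisible(fx)
}

#' Read / write a distance-bearing log
#'
#' The DB-log CSV dialect has one row per measured movement step:
#' `track_id, order, distance_m, azimuth_deg, frame` where `frame` is
#' `"magnetic"` or `"true"` and `order` numbers steps from 1 within a track.
#'
#' @param path File path.
#' @return `read_db_log()` returns a validated data.frame.
#' @export
read_db_log <- function(path) {
  db <- read.csv(path, stringsAsFactors = FALSE)
  validate_db_log(db)
  db
}

#' @rdname read_db_log
#' @param db A DB-log data.frame as described above.
#' @export
write_db_log <- function(db, path) {
  validate_db_log(db)
  write.csv(db, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_db_log <- function(db) {
  need <- c("track_id", "order", "distance_m", "azimuth_deg", "frame")
  miss <- setdiff(need, names(db))
  if (length(miss))
    stop("DB log missing column(s): ", paste(miss, collapse = ", "))
  if (any(db$distance_m <= 0)) stop("distances must be > 0")
  if (any(db$azimuth_deg < 0 | db$azimuth_deg >= 360))
    stop("azimuths must be in [0, 360)")
  if (any(!db$frame %in% c("magnetic", "true")))
    stop("frame must be 'magnetic' or 'true'")
  invisible(db)
}

#' Export one track as a GeoJSON LineString
#'
#' Writes an RFC 7946 FeatureCollection holding a single LineString in WGS84,
#' with `track_id` and `method` as feature properties and optionally a
#' per-vertex decoded movement state array.
#'
#' @param fixes Fix data.frame rows for one track (ordered by `order`).
#' @param path Output path.
#' @param states Optional integer vector of decoded states, one per step
#'   (attached as property `states`).
#' @return `path`, invisibly.
#' @export
write_track_geojson <- function(fixes, path, states = NULL) {
  stopifnot(length(unique(fixes$track_id)) == 1)
  fixes <- fixes[order(fixes$order), ]
  props <- list(track_id = fixes$track_id[1], method = fixes$method[1])
  if (!is.null(states)) props$states <- as.integer(states)
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(fixes)),
                             function(i) c(fixes$lon[i], fixes$lat[i]))
      )
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a fix table to a list of step series
#'
#' Splits a fix data.frame by track and derives each track's
#' [step_series][coords_to_steps()] from its coordinates.
#'
#' @param fixes Fix data.frame (any number of tracks).
#' @param min_distance Passed to [coords_to_steps()].
#' @return Named list of `step_series`, one per `track_id`.
#' @export
fixes_to_series <- function(fixes, min_distance = 0) {
  ids <- unique(fixes$track_id)
  out <- lapply(ids, function(id) {
    tr <- fixes[fixes$track_id == id, ]
    tr <- tr[order(tr$order), ]
    coords_to_steps(tr$lon, tr$lat, min_distance = min_distance)
  })
  names(out) <- ids
  out
}
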