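# File interfaces: CSV readers/writers for photo records, deployment
# effort, telemetry, capture histories and trap arrays; GeoJSON masks;
# JSON run configuration. Coordinates are planar km throughout --
# projecting from geographic coordinates is the caller's responsibility.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(df)) stop(what, " file ", path, " has no data rows", call. = FALSE)
  df
}

parse_time <- function(x, path, col) {
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  t <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  for (f in fmts) {
    need <- is.na(t)
    if (!any(need)) break
    t[need] <- as.POSIXct(strptime(x[need], f, tz = "UTC"))
  }
  bad <- which(is.na(t) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop("unparseable ", col, " in ", path, " at data row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  t
}

#' Read camera photo records
#'
#' CSV columns: `camera_id`, `timestamp` (ISO-8601), `species`.
#'
#' @param path CSV file.
#' @param species Optional species filter; excluded rows are counted in a
#'   message.
#' @return Sorted data frame of photo records.
#' @export
read_photo_records <- function(path, species = NULL) {
  df <- read_csv_checked(path, c("camera_id", "timestamp", "species"),
                         "photo records")
  df$timestamp <- parse_time(df$timestamp, path, "timestamp")
  if (!is.null(species)) {
    drop <- df$species != species
    if (any(drop)) message(sum(drop), " record(s) of other species excluded")
    df <- df[!drop, , drop = FALSE]
  }
  df <- df[order(df$camera_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read the camera deployment / effort table
#'
#' CSV columns: `camera_id`, `x_km`, `y_km`, `start`, `end` (ISO-8601),
#' `r_m`, `r_se_m`, `theta_rad`, `theta_se_rad`. Computes `active_days`
#' from the half-open deployment window.
#'
#' @param path CSV file.
#' @return Data frame with an `active_days` column added.
#' @export
read_effort_table <- function(path) {
  df <- read_csv_checked(path, c("camera_id", "x_km", "y_km", "start", "end",
                                 "r_m", "r_se_m", "theta_rad", "theta_se_rad"),
                         "effort")
  df$start <- parse_time(df$start, path, "start")
  df$end <- parse_time(df$end, path, "end")
  df$active_days <- as.numeric(difftime(df$end, df$start, units = "days"))
  if (any(df$active_days <= 0))
    stop("non-positive deployment duration in ", path, call. = FALSE)
  df
}

#' Effort-weighted mean detection zone of a camera array
#'
#' Different camera models have different zones; the REM uses the
#' effort-weighted means of r and theta, with standard errors combined by
#' the same weights.
#'
#' @param efforts Output of [read_effort_table()] (or a frame with
#'   `active_days`, `r_m`, `r_se_m`, `theta_rad`, `theta_se_rad`).
#' @return A [detection_zone()] in km/radians.
#' @export
pooled_zone <- function(efforts) {
  w <- efforts$active_days / sum(efforts$active_days)
  detection_zone(radius_r = sum(w * efforts$r_m) / 1000,
                 arc_theta = sum(w * efforts$theta_rad),
                 radius_se = sqrt(sum((w * efforts$r_se_m)^2)) / 1000,
                 arc_se = sqrt(sum((w * efforts$theta_se_rad)^2)))
}

#' Read GPS telemetry fixes
#'
#' CSV columns: `animal_id`, `population`, `timestamp` (ISO-8601),
#' `x_km`, `y_km` (planar).
#'
#' @param path CSV file.
#' @return Data frame ready for [segment_speeds()] (columns renamed to
#'   `x`, `y`).
#' @export
read_telemetry <- function(path) {
  df <- read_csv_checked(path, c("animal_id", "population", "timestamp",
                                 "x_km", "y_km"), "telemetry")
  df$timestamp <- parse_time(df$timestamp, path, "timestamp")
  names(df)[names(df) == "x_km"] <- "x"
  names(df)[names(df) == "y_km"] <- "y"
  df[order(df$animal_id, df$timestamp), , drop = FALSE]
}

#' Read an SCR capture-history CSV
#'
#' Columns: `individual_id`, `trap_id`, `occasion` (1-based), optional
#' `sex` (`M`/`F`/anything else = unknown).
#'
#' @param path CSV file.
#' @param n_occasions Total occasions (default max observed).
#' @param trap_ids Optional full trap list (for traps with no captures).
#' @return A [capture_history()].
#' @export
read_capture_history <- function(path, n_occasions = NULL, trap_ids = NULL) {
  df <- read_csv_checked(path, c("individual_id", "trap_id", "occasion"),
                         "capture history")
  sex <- NULL
  if ("sex" %in% names(df)) {
    first <- !duplicated(df$individual_id)
    sex <- setNames(df$sex[first], df$individual_id[first])
  }
  capture_history(df, sex = sex, n_occasions = n_occasions,
                  trap_ids = trap_ids)
}

#' Read a trap/camera coordinate table
#'
#' CSV columns: `trap_id`, `x_km`, `y_km`.
#'
#' @param path CSV file.
#' @return Data frame `trap_id`, `x`, `y` (km).
#' @export
read_trap_array <- function(path) {
  df <- read_csv_checked(path, c("trap_id", "x_km", "y_km"), "trap array")
  data.frame(trap_id = as.character(df$trap_id), x = df$x_km, y = df$y_km)
}

#' Read the first polygon of a GeoJSON file as a mask
#'
#' Accepts a Polygon geometry, a Feature wrapping one, or a
#' FeatureCollection (first feature used). Coordinates are taken as
#' planar km, matching the rest of the package.
#'
#' @param path GeoJSON file.
#' @return Two-column matrix of polygon vertices.
#' @export
read_mask_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (identical(g$type, "FeatureCollection")) g$features$geometry else
    if (identical(g$type, "Feature")) g$geometry else g
  coords <- geom$coordinates
  while (is.list(coords)) coords <- coords[[1]]
  if (length(dim(coords)) == 3) coords <- coords[1, , ]
  m <- matrix(as.numeric(coords), ncol = 2,
              dimnames = list(NULL, c("x", "y")))
  if (nrow(m) < 3) stop("mask polygon needs at least 3 vertices", call. = FALSE)
  m
}

#' Write synthetic photo records / telemetry / captures / traps / effort
#'
#' Writers emit the same CSV dialects the readers consume, so simulated
#' data round-trip through the full pipeline.
#'
#' @param records,fixes,history,traps,efforts Objects to write.
#' @param path Output CSV path.
#' @param species Species label stamped on photo records.
#' @return The path, invisibly.
#' @name writers
NULL

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' @rdname writers
#' @export
write_photo_records <- function(records, path, species = "target") {
  df <- data.frame(camera_id = records$camera_id,
                   timestamp = fmt_time(records$timestamp),
                   species = if ("species" %in% names(records))
                     records$species else species)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_telemetry <- function(fixes, path) {
  df <- data.frame(animal_id = fixes$animal_id,
                   population = if ("population" %in% names(fixes))
                     fixes$population else "sim",
                   timestamp = fmt_time(fixes$timestamp),
                   x_km = fixes$x, y_km = fixes$y)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_capture_history <- function(history, path) {
  stopifnot(inherits(history, "capture_history"))
  df <- history$captures
  df$sex <- history$sex[df$individual_id]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_trap_array <- function(traps, path) {
  write.csv(data.frame(trap_id = traps$trap_id, x_km = traps$x,
                       y_km = traps$y),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_effort_table <- function(efforts, path) {
  write.csv(efforts[c("camera_id", "x_km", "y_km", "start", "end", "r_m",
                      "r_se_m", "theta_rad", "theta_se_rad")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
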