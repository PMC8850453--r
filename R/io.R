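#' Write / read trajectory tables
#'
#' Plain-text CSV round-tripping of trajectory tables (comma separator,
#' period decimal, mandatory header `t, agent_id, x, y, vx, vy, chirality`).
#' Coordinates survive the round trip to better than 1e-12. Simulation
#' metadata (parameters and run configuration) is written to a JSON sidecar
#' `<path>.meta.json` and re-attached on read when present.
#'
#' `read_trajectory` is tolerant toward external tracking exports: columns
#' can be remapped by name, velocity columns may be absent (the table is
#' then flagged positions-only and [sliding_velocities()] is required
#' downstream), and non-uniform time stamps trigger a warning.
#'
#' @param traj A `ped_trajectory` (or compatible data.frame).
#' @param path CSV file path.
#' @param write_meta Write the metadata sidecar?
#' @param col_map Named character vector mapping the expected column names
#'   to the names found in the file, e.g.
#'   `c(t = "time", agent_id = "id", x = "px", y = "py")`.
#' @param arena Arena to attach (defaults to the sidecar's, else the
#'   standard arena).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `ped_trajectory`.
#' @export
write_trajectory <- function(traj, path, write_meta = TRUE) {
  cols <- intersect(c("t", "agent_id", "x", "y", "vx", "vy", "chirality"),
                    names(traj))
  data.table::fwrite(data.table::as.data.table(traj)[, cols, with = FALSE],
                     path)
  if (write_meta) {
    config <- attr(traj, "config")
    params <- attr(traj, "params")
    arena <- attr(traj, "arena")
    meta <- list(
      config = if (!is.null(config)) unclass(config),
      params = if (!is.null(params)) unclass(params),
      arena = if (!is.null(arena)) list(width = arena$width,
                                        height = arena$height))
    meta <- Filter(Negate(is.null), meta)
    if (length(meta)) {
      jsonlite::write_json(meta, paste0(path, ".meta.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, col_map = NULL, arena = NULL) {
  dt <- data.table::fread(path)
  if (nrow(dt) == 0L) stop(sprintf("'%s': no data rows (header-only file?)", path))
  if (!is.null(col_map)) {
    data.table::setnames(dt, unname(col_map), names(col_map),
                         skip_absent = TRUE)
  }
  required <- c("t", "agent_id", "x", "y")
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop(sprintf("'%s': missing required column(s) %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (cc in intersect(c("t", "x", "y", "vx", "vy"), names(dt))) {
    if (!is.numeric(dt[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[cc]]))))[1]
      stop(sprintf("'%s': non-numeric value in column '%s' (data line %d)",
                   path, cc, if (is.na(bad)) NA_integer_ else bad))
    }
  }
  if (!"chirality" %in% names(dt)) dt[, chirality := NA_integer_]
  positions_only <- !all(c("vx", "vy") %in% names(dt))

  # frame-rate sanity: uniform spacing expected per agent
  tg <- sort(unique(dt$t))
  if (length(tg) > 2L) {
    dts <- diff(tg)
    if ((max(dts) - min(dts)) > 1e-6 * stats::median(dts)) {
      warning(sprintf("'%s': non-uniform time steps (median %.4g s); consider resampling",
                      path, stats::median(dts)))
    }
  }

  config <- NULL; params <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$arena) && is.null(arena)) {
      arena <- pedvortex::arena(meta$arena$width, meta$arena$height)
    }
    if (!is.null(meta$params)) params <- do.call(model_params, meta$params)
    if (!is.null(meta$config)) config <- do.call(sim_config, meta$config)
  }
  if (is.null(arena)) arena <- pedvortex::arena()
  out <- new_trajectory(dt, config = config, params = params, arena = arena)
  data.table::setattr(out, "positions_only", positions_only)
  out
}

#' Write / read an angular-momentum series
#'
#' Two-column plain-text table (`t`, `L`).
#'
#' @param series An [l_series()] result.
#' @param path File path.
#' @export
write_l_series <- function(series, path) {
  data.table::fwrite(data.table::as.data.table(series)[, c("t", "L")], path)
  invisible(path)
}

#' @rdname write_l_series
#' @export
read_l_series <- function(path) {
  out <- data.table::fread(path)
  stopifnot(all(c("t", "L") %in% names(out)))
  data.table::setattr(out, "class", unique(c("l_series", class(out))))
  out
}

#' Export a turn-event table
#'
#' @param events Table from [detect_turn_events()].
#' @param path CSV path.
#' @export
write_turn_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}
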