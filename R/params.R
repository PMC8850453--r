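#' Model parameters
#'
#' Bundle of all physical constants of the force laws. Defaults are the
#' calibrated set used throughout: propulsion gain `mu = 4` and desired speed
#' `v_d = 1.5` m/s (matching observed walking-speed distributions), agent
#' radius `r0 = 0.25` m, social repulsion amplitude `A_p = 13` with decay
#' length `B_p = 0.85` m (calibrated on Voronoi-area distributions), Hertzian
#' contact strength `eps = 200`, wall repulsion amplitude `A_w1 = 15` with
#' decay length `B_w = 0.4` m, turning-force amplitude `A_w2 = 9`, and wall
#' damping `gamma` in `[0, 2]` (the control parameter of the vortex
#' transition; default 0 = no damping).
#'
#' @param mu Propulsion gain (SI units, force per unit speed at unit mass).
#' @param v_d Desired walking speed, m/s.
#' @param r0 Agent radius, m.
#' @param A_p Agent-agent long-range repulsion amplitude.
#' @param B_p Agent-agent repulsion decay length, m.
#' @param eps Hertzian contact strength (shared by agent and wall contacts).
#' @param A_w1 Wall repulsion amplitude.
#' @param A_w2 Turning-force amplitude.
#' @param B_w Wall force decay length, m.
#' @param gamma Wall damping coefficient (>= 0).
#' @param mass Agent mass; unit mass by default so the propulsion relaxation
#'   time is `mass/mu` = 0.25 s.
#' @param tp_enabled Logical; apply the tangential turning-preference force?
#' @param tp_ccw_fraction Fraction of agents preferring counterclockwise
#'   turns (chirality +1) when `tp_enabled`.
#' @param damping_range Distance from the wall surface (measured as
#'   `r_iw - r0`) within which the `-gamma * v_n` damping term acts; `Inf`
#'   reproduces the unbounded, literal reading of the force law. Default 1 m
#'   localizes dissipation at the boundary.
#' @param wall_mode `"all_walls"` (sum the wall forces over all four walls;
#'   default, smooth at corners) or `"nearest_only"` (only the nearest wall).
#' @return An object of class `ped_params` (a validated list).
#' @examples
#' p <- model_params(gamma = 1.5)
#' p$A_w1
#' @export
model_params <- function(mu = 4, v_d = 1.5, r0 = 0.25,
                         A_p = 13, B_p = 0.85, eps = 200,
                         A_w1 = 15, A_w2 = 9, B_w = 0.4,
                         gamma = 0, mass = 1,
                         tp_enabled = FALSE, tp_ccw_fraction = 0.6,
                         damping_range = 1.0,
                         wall_mode = c("all_walls", "nearest_only")) {
  wall_mode <- match.arg(wall_mode)
  p <- list(mu = mu, v_d = v_d, r0 = r0, A_p = A_p, B_p = B_p, eps = eps,
            A_w1 = A_w1, A_w2 = A_w2, B_w = B_w, gamma = gamma, mass = mass,
            tp_enabled = isTRUE(tp_enabled),
            tp_ccw_fraction = tp_ccw_fraction,
            damping_range = damping_range, wall_mode = wall_mode)
  validate_params(p)
  structure(p, class = "ped_params")
}

validate_params <- function(p) {
  pos <- c("mu", "v_d", "r0", "A_p", "B_p", "eps", "A_w1", "A_w2", "B_w",
           "mass", "damping_range")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !(p[[nm]] > 0)) {
      stop(sprintf("parameter '%s' must be a single strictly positive number", nm))
    }
  }
  if (!is.numeric(p$gamma) || p$gamma < 0) stop("gamma must be >= 0")
  if (p$tp_ccw_fraction < 0 || p$tp_ccw_fraction > 1) {
    stop("tp_ccw_fraction must lie in [0, 1]")
  }
  if (!p$wall_mode %in% c("all_walls", "nearest_only")) {
    stop("wall_mode must be 'all_walls' or 'nearest_only'")
  }
  invisible(p)
}

#' @export
print.ped_params <- function(x, ...) {
  cat("<ped_params>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write / read a parameter set as a flat key = value config file
#'
#' Plain-text serialization with one `key = value` pair per line; the file
#' round-trips exactly through [read_params()] (numbers are written with
#' full double precision).
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `ped_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ped_params"))
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) ifelse(v, "true", "false")
    else format(v, digits = 17)
  }
  lines <- vapply(names(params),
                  function(nm) paste(nm, "=", fmt(params[[nm]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), character(1))
  args <- stats::setNames(as.list(vals), keys)
  args <- lapply(args, function(v) {
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(model_params, args)
}
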