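#' Clearance radius at a point inside a structure
#'
#' Radius of the largest sphere centred at `point` that touches no atom's
#' van der Waals surface: the minimum over atoms of (distance to the atom
#' centre minus the atom's van der Waals radius). A negative value means
#' the point lies inside an atom; it is returned as-is so callers can
#' detect wall penetration.
#'
#' @param model a [structure_model()].
#' @param point numeric length-3 coordinates, Angstrom.
#' @return clearance radius in Angstrom (possibly negative).
#' @export
clearance_radius <- function(model, point) {
  stopifnot(inherits(model, "structure_model"), length(point) == 3L)
  a <- model$atom
  if (nrow(a) == 0L) stop("empty structure")
  d <- sqrt((a$x - point[1])^2 + (a$y - point[2])^2 + (a$z - point[3])^2)
  min(d - vdw_radius(a$elesy))
}

#' Trace a clearance-radius profile along a path
#'
#' Resamples a polyline at fixed arc-length steps (endpoints always
#' included) and evaluates [clearance_radius()] at every station. If the
#' path runs into an atom (clearance <= 0) the profile is truncated at the
#' last open station with a warning.
#'
#' @param model a [structure_model()].
#' @param path matrix or data.frame of waypoints (columns x, y, z), at
#'   least 2 rows.
#' @param step station spacing along the path, Angstrom.
#' @return a `tunnel_profile`: data.frame (`s`, `x`, `y`, `z`, `r`) with
#'   attribute `source = "traced"`.
#' @export
trace_profile <- function(model, path, step = 0.5) {
  path <- as.matrix(path)[, 1:3, drop = FALSE]
  if (nrow(path) < 2L) stop("path needs at least 2 points")
  if (step <= 0) stop("step must be positive")
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total == 0) stop("degenerate zero-length path")
  s_knots <- c(0, cumsum(seg_len))
  s_out <- unique(sort(c(seq(0, total, by = step), total)))
  interp <- function(col) approx(s_knots, path[, col], xout = s_out)$y
  pts <- cbind(interp(1), interp(2), interp(3))
  r <- vapply(seq_along(s_out), function(i)
    clearance_radius(model, pts[i, ]), numeric(1))
  closed <- which(r <= 0)
  if (length(closed)) {
    keep <- seq_len(min(closed) - 1L)
    warning(sprintf("path blocked at s = %.2f A; profile truncated",
                    s_out[min(closed)]))
    if (!length(keep)) stop("path is blocked at its start")
    s_out <- s_out[keep]; pts <- pts[keep, , drop = FALSE]; r <- r[keep]
  }
  out <- data.frame(s = s_out, x = pts[, 1], y = pts[, 2], z = pts[, 3], r = r)
  attr(out, "source") <- "traced"
  class(out) <- c("tunnel_profile", "data.frame")
  out
}

#' Volume of a right conical frustum
#'
#' `V = pi h (r1^2 + r1 r2 + r2^2) / 3`; symmetric in the two end radii,
#' and equal to a cylinder when `r1 = r2` and a cone when one radius is 0.
#'
#' @param r1,r2 end radii, Angstrom (nonnegative).
#' @param h height, Angstrom (positive). Vectorised.
#' @return volume(s) in Angstrom^3.
#' @export
#' @examples
#' frustum_volume(1, 1, 3)  # cylinder: 3*pi
#' frustum_volume(1, 0, 3)  # cone: pi
frustum_volume <- function(r1, r2, h) {
  if (any(r1 < 0) || any(r2 < 0)) stop("radii must be nonnegative")
  if (any(h <= 0)) stop("height must be positive")
  pi * h * (r1^2 + r1 * r2 + r2^2) / 3
}

profile_radius_at <- function(profile, s) {
  approx(profile$s, profile$r, xout = s)$y
}

#' Frustum-sum volume of a profile segment
#'
#' Sums [frustum_volume()] over consecutive stations of a clearance-radius
#' profile between `s_start` and `s_end`; partial frustums at the cut
#' boundaries use linearly interpolated radii.
#'
#' @param profile a `tunnel_profile` (from [trace_profile()] or
#'   [import_profile()]).
#' @param s_start,s_end segment bounds in arc-length, Angstrom; default to
#'   the full profile.
#' @return volume in Angstrom^3.
#' @export
profile_volume <- function(profile, s_start = min(profile$s),
                           s_end = max(profile$s)) {
  stopifnot(inherits(profile, "tunnel_profile"))
  if (s_end <= s_start) stop("s_end must exceed s_start")
  if (s_start < min(profile$s) - 1e-9 || s_end > max(profile$s) + 1e-9)
    stop(sprintf("bounds [%.2f, %.2f] outside profile range [%.2f, %.2f]",
                 s_start, s_end, min(profile$s), max(profile$s)))
  inside <- profile$s > s_start & profile$s < s_end
  ss <- c(s_start, profile$s[inside], s_end)
  rr <- c(profile_radius_at(profile, s_start), profile$r[inside],
          profile_radius_at(profile, s_end))
  sum(frustum_volume(rr[-length(rr)], rr[-1], diff(ss)))
}

#' Pinch points of a clearance-radius profile
#'
#' A pinch point is a local constriction: the tunnel narrows, then widens
#' again. Reported are the arc-lengths of local radius minima whose depth
#' below both flanking maxima is at least `min_prominence`; monotone
#' profiles have none.
#'
#' @param profile a `tunnel_profile`.
#' @param min_prominence required narrowing depth on both sides, Angstrom.
#' @return numeric vector of arc-lengths (possibly empty), ordered by s.
#' @export
find_pinch_points <- function(profile, min_prominence = 0.2) {
  stopifnot(inherits(profile, "tunnel_profile"))
  r <- profile$r
  s <- profile$s
  n <- length(r)
  if (n < 3L) stop("profile needs at least 3 stations")
  out <- numeric(0)
  for (i in 2:(n - 1L)) {
    if (!(r[i] < r[i - 1L] && r[i] <= r[i + 1L])) next
    left_max <- max(r[1:(i - 1L)])
    right_max <- max(r[(i + 1L):n])
    if (min(left_max, right_max) - r[i] >= min_prominence)
      out <- c(out, s[i])
  }
  out
}

#' Active-site segment of a tunnel profile
#'
#' Cuts the innermost `length` Angstrom of the profile (measured in
#' arc-length from `s_start`), integrates its frustum-sum volume, and
#' attaches any pinch points falling inside the segment. The default
#' 10.5 Angstrom bound is the consensus first-pinch-point distance used to
#' delimit alpha/beta-hydrolase active sites.
#'
#' @param profile a `tunnel_profile`.
#' @param s_start segment start, Angstrom arc-length.
#' @param length segment length, Angstrom.
#' @param min_prominence passed to [find_pinch_points()].
#' @return object of class `active_site_segment`: `s_start`, `s_end`,
#'   `volume` (Angstrom^3), `pinch_points`.
#' @export
active_site_volume <- function(profile, s_start = 0, length = 10.5,
                               min_prominence = 0.2) {
  stopifnot(inherits(profile, "tunnel_profile"))
  s_end <- s_start + length
  if (max(profile$s) < s_end)
    stop(sprintf(paste0("profile ends at %.2f A but the segment needs ",
                        "%.2f A; achievable length %.2f A"),
                 max(profile$s), s_end, max(profile$s) - s_start))
  pp <- find_pinch_points(profile, min_prominence)
  structure(list(s_start = s_start, s_end = s_end,
                 volume = profile_volume(profile, s_start, s_end),
                 pinch_points = pp[pp >= s_start & pp <= s_end]),
            class = "active_site_segment")
}

#' @export
print.active_site_segment <- function(x, ...) {
  cat(sprintf("active-site segment [%.2f, %.2f] A: volume %.1f A^3\n",
              x$s_start, x$s_end, x$volume))
  if (length(x$pinch_points))
    cat("  pinch points at s =", paste(sprintf("%.2f", x$pinch_points),
                                       collapse = ", "), "A\n")
  invisible(x)
}

#' Import a tunnel profile from a table
#'
#' Accepts a CSV path or data.frame with columns `s`/`s_A`, `x`, `y`, `z`,
#' `r`/`r_A`. Rows are sorted by arc-length; duplicate arc-lengths and
#' nonpositive radii are errors. The resulting profile behaves identically
#' to a traced one in all volumetric operations.
#'
#' @param table data.frame or path to a CSV file with a header row.
#' @return a `tunnel_profile` with attribute `source = "imported"`.
#' @export
import_profile <- function(table) {
  if (is.character(table)) table <- read.csv(table)
  stopifnot(is.data.frame(table))
  nm <- names(table)
  pick <- function(...) {
    for (k in c(...)) if (k %in% nm) return(table[[k]])
    stop("profile table missing column: ", ..1)
  }
  out <- data.frame(s = pick("s", "s_A"), x = pick("x"), y = pick("y"),
                    z = pick("z"), r = pick("r", "r_A"))
  out <- out[order(out$s), , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$s)) stop("duplicate arc-length values in profile")
  if (any(out$r <= 0)) stop("profile radii must be positive")
  attr(out, "source") <- "imported"
  class(out) <- c("tunnel_profile", "data.frame")
  out
}

#' Export a tunnel profile to CSV
#'
#' Writes the standard `s_A, x, y, z, r_A` layout read back by
#' [import_profile()].
#'
#' @param profile a `tunnel_profile`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_profile <- function(profile, file) {
  stopifnot(inherits(profile, "tunnel_profile"))
  out <- data.frame(s_A = profile$s, x = profile$x, y = profile$y,
                    z = profile$z, r_A = profile$r)
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}
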