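#' Construct the eye coordinate frame
#'
#' The eye is a sphere of outer diameter `diameter` (mm) with a concentric
#' scleral shell of thickness `sclera` (mm).  The coordinate frame is anchored
#' beneath the plaque: the origin (Z = 0) is the inner sclera point on the
#' plaque central axis, Z increases into the eye, and Z = -`sclera` is the
#' outer sclera / plaque interface.  With the defaults (24.6 mm, 1.0 mm) the
#' eyeball centre is at Z = 11.3 mm and the opposite-pole inner retina at
#' Z = 22.6 mm.
#'
#' @param diameter Outer eyeball diameter in mm (default 24.6).
#' @param sclera Scleral thickness in mm (default 1.0).
#' @return An object of class `eye_model` with fields `diameter`, `sclera`,
#'   `inner_radius` (mm) and `center_z` (mm, = inner radius).
#' @export
#' @examples
#' eye <- make_eye()
#' eye$center_z                        # 11.3 mm
make_eye <- function(diameter = 24.6, sclera = 1.0) {
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be positive")
  if (!is.finite(sclera) || sclera < 0) stop("sclera thickness must be >= 0")
  if (diameter <= 2 * sclera) stop("diameter must exceed twice the scleral thickness")
  inner_radius <- (diameter - 2 * sclera) / 2
  structure(list(diameter = diameter, sclera = sclera,
                 inner_radius = inner_radius, center_z = inner_radius),
            class = "eye_model")
}

#' Construct the tumor model
#'
#' The tumor is an ellipsoidal dome anchored on the inner sclera at Z = 0:
#' points with (x/a)^2 + (y/b)^2 + (z/h)^2 <= 1 and z >= 0 (a, b the base
#' semi-axes, h the apical height), intersected with the eyeball interior
#' (the base rim of a wide dome is trimmed by the curved sclera).
#'
#' @param eye An [make_eye()] model.
#' @param major Base diameter along x in mm (default 12).
#' @param minor Base diameter along y in mm (default 12).
#' @param height Apical height in mm (default 6).
#' @return An object of class `tumor_model`.
#' @export
make_tumor <- function(eye, major = 12, minor = 12, height = 6) {
  stopifnot(inherits(eye, "eye_model"))
  if (any(!is.finite(c(major, minor, height))) || any(c(major, minor, height) <= 0))
    stop("tumor dimensions must be positive")
  if (height > eye$diameter)
    stop("tumor height exceeds the eyeball diameter")
  structure(list(a = major / 2, b = minor / 2, h = height,
                 major = major, minor = minor, height = height, eye = eye),
            class = "tumor_model")
}

#' Region membership predicate
#'
#' Tests which 3D points (eye frame, mm) lie inside a region: the eyeball
#' interior (inner-sclera sphere) for an `eye_model`, or the ellipsoidal dome
#' intersected with the eyeball for a `tumor_model`.
#'
#' @param region An `eye_model` or `tumor_model`.
#' @param points Numeric matrix with columns x, y, z in mm (a single point
#'   may be given as a length-3 vector).
#' @return Logical vector, one entry per point.
#' @export
region_contains <- function(region, points) UseMethod("region_contains")

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have three columns (x, y, z in mm)")
  storage.mode(points) <- "double"
  points
}

#' @export
region_contains.eye_model <- function(region, points) {
  p <- .as_points(points)
  p[, 1]^2 + p[, 2]^2 + (p[, 3] - region$center_z)^2 <= region$inner_radius^2
}

#' @export
region_contains.tumor_model <- function(region, points) {
  p <- .as_points(points)
  dome <- (p[, 1] / region$a)^2 + (p[, 2] / region$b)^2 +
    (p[, 3] / region$h)^2 <= 1 & p[, 3] >= 0
  dome & region_contains(region$eye, p)
}

#' Analytic volume of the untruncated tumor dome
#'
#' Volume of the half-ellipsoid (2/3) * pi * a * b * h in mm^3, ignoring the
#' eyeball truncation.  Used as an oracle for membership-based estimates when
#' the dome lies entirely inside the eye.
#'
#' @param tumor A [make_tumor()] model.
#' @return Volume in mm^3.
#' @export
dome_volume <- function(tumor) {
  stopifnot(inherits(tumor, "tumor_model"))
  2 / 3 * pi * tumor$a * tumor$b * tumor$h
}

# Place n seeds on a ring of transverse radius rho_mm (distance from the
# plaque axis) on the seed-centre sphere of radius Rs_mm about the eye
# centre.  Orientations are azimuthal: tangent both to the sphere and to the
# ring.  Positions are returned in cm (TG-43 native unit).
.place_ring <- function(eye, rho_mm, n, phase_deg, depth_mm) {
  Rs <- eye$inner_radius + depth_mm
  if (rho_mm >= Rs)
    stop("ring transverse radius ", rho_mm, " mm exceeds the seed-centre sphere radius")
  phi <- (phase_deg + (seq_len(n) - 1) * 360 / n) * pi / 180
  z <- eye$center_z - sqrt(Rs^2 - rho_mm^2)
  pos <- cbind(x = rho_mm * cos(phi), y = rho_mm * sin(phi),
               z = rep(z, length(phi))) / 10
  ori <- cbind(-sin(phi), cos(phi), rep(0, length(phi)))
  list(pos = pos, ori = ori)
}

.plaque_model <- function(name, diameter, pos_cm, ori, depth_mm, eye) {
  nrm <- sqrt(rowSums(ori^2))
  ori <- ori / nrm
  if (any(region_contains(eye, pos_cm * 10)))
    stop("seed centre(s) fall inside the eyeball interior")
  structure(list(name = name, diameter = diameter,
                 seeds = pos_cm, orientations = ori,
                 n_seeds = nrow(pos_cm), seed_center_depth = depth_mm),
            class = "plaque_model")
}

#' @export
print.plaque_model <- function(x, ...) {
  cat("Plaque:", x$name, sprintf("(%g mm, %d seeds, seed-centre depth %g mm)\n",
                                 x$diameter, x$n_seeds, x$seed_center_depth))
  invisible(x)
}

#' 16 mm COMS plaque seed configuration
#'
#' Thirteen equal-strength seeds approximating three isocentric circles:
#' one central seed, an inner ring of 4 and an outer ring of 8.  Seed centres
#' lie on a sphere concentric with the eye at `seed_center_depth` mm behind
#' the inner sclera (default 2.75 mm = 1.0 mm sclera + 1.75 mm carrier
#' seed-plane offset); orientations are tangential to that sphere and tangent
#' to each ring.  All radii and depths are configurable so that transcribed
#' literature coordinates can be substituted.
#'
#' @param eye An [make_eye()] model.
#' @param ring_radii Transverse radii of the rings in mm (default 3.0, 5.8).
#' @param ring_counts Seeds per ring (default 4, 8).
#' @param ring_phases Azimuthal phase of each ring in degrees (default 0,
#'   22.5: the outer ring is staggered relative to the inner one).
#' @param central Include the central seed (default `TRUE`).
#' @param seed_center_depth Depth of the seed-centre sphere behind the inner
#'   sclera, mm.
#' @param diameter Plaque diameter in mm (default 16).
#' @return An object of class `plaque_model`; `$seeds` is an n x 3 matrix of
#'   seed centres in cm, `$orientations` the unit long-axis vectors.
#' @export
#' @examples
#' plq <- coms16_plaque(make_eye())
#' plq$n_seeds    # 13
coms16_plaque <- function(eye = make_eye(), ring_radii = c(3.0, 5.8),
                          ring_counts = c(4L, 8L), ring_phases = c(0, 22.5),
                          central = TRUE, seed_center_depth = 2.75,
                          diameter = 16) {
  stopifnot(inherits(eye, "eye_model"),
            length(ring_radii) == length(ring_counts),
            length(ring_radii) == length(ring_phases))
  if (any(ring_radii > diameter / 2))
    stop("ring transverse radius exceeds the plaque radius")
  Rs <- eye$inner_radius + seed_center_depth
  pos <- NULL; ori <- NULL
  if (central) {
    pos <- matrix(c(0, 0, (eye$center_z - Rs) / 10), 1, 3)
    ori <- matrix(c(1, 0, 0), 1, 3)    # tangential; azimuth arbitrary on axis
  }
  for (k in seq_along(ring_radii)) {
    rg <- .place_ring(eye, ring_radii[k], ring_counts[k], ring_phases[k],
                      seed_center_depth)
    pos <- rbind(pos, rg$pos)
    ori <- rbind(ori, rg$ori)
  }
  .plaque_model("COMS-16", diameter, pos, ori, seed_center_depth, eye)
}

#' 16 mm OSU-NAG plaque seed configuration
#'
#' Eight equal-strength seeds glued directly to the plaque shell, forming two
#' concentric squares: an inner square of 4 (transverse half-diagonal 3.0 mm)
#' and an outer square of 4 rotated 45 degrees (half-diagonal 5.5 mm).  Seed
#' centres lie `seed_center_depth` mm behind the inner sclera (default
#' 1.4 mm = 1.0 mm sclera + 0.4 mm seed radius, since the seeds rest on the
#' shell); orientations are tangential.
#'
#' @param eye An [make_eye()] model.
#' @param inner_half_diagonal Transverse half-diagonal of the inner square, mm.
#' @param outer_half_diagonal Transverse half-diagonal of the outer square, mm.
#' @param inner_phase Azimuth of the first inner-square seed, degrees.
#' @param seed_center_depth Depth of seed centres behind the inner sclera, mm.
#' @param diameter Plaque diameter in mm (default 16).
#' @return An object of class `plaque_model` (see [coms16_plaque()]).
#' @export
#' @examples
#' nag16_plaque(make_eye())$n_seeds   # 8
nag16_plaque <- function(eye = make_eye(), inner_half_diagonal = 3.0,
                         outer_half_diagonal = 5.5, inner_phase = 0,
                         seed_center_depth = 1.4, diameter = 16) {
  stopifnot(inherits(eye, "eye_model"))
  if (any(c(inner_half_diagonal, outer_half_diagonal) > diameter / 2))
    stop("square half-diagonal exceeds the plaque radius")
  inner <- .place_ring(eye, inner_half_diagonal, 4L, inner_phase,
                       seed_center_depth)
  outer <- .place_ring(eye, outer_half_diagonal, 4L, inner_phase + 45,
                       seed_center_depth)
  .plaque_model("OSU-NAG-16", diameter,
                rbind(inner$pos, outer$pos), rbind(inner$ori, outer$ori),
                seed_center_depth, eye)
}

#' Read a plaque configuration file
#'
#' Plain-text `key: value` format; comment lines start with `#`.  The `type`
#' key selects the generator (`coms16` or `nag16`); remaining keys override
#' that generator's defaults.  Example files for both plaques ship under
#' `system.file("extdata", package = "eyeplaque")`.
#'
#' @param path Path to the configuration file.
#' @param eye An [make_eye()] model (default standard eye).
#' @return A `plaque_model`.
#' @export
#' @examples
#' cfg <- system.file("extdata", "coms16.cfg", package = "eyeplaque")
#' read_plaque_config(cfg)
read_plaque_config <- function(path, eye = make_eye()) {
  if (!file.exists(path)) stop("plaque config file not found: ", path)
  raw <- trimws(readLines(path, warn = FALSE))
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  kv <- list()
  for (line in raw) {
    parts <- strsplit(line, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: '", line, "'")
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  if (is.null(kv$type)) stop("plaque config must name a 'type' (coms16 or nag16)")
  nums <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(strsplit(kv[[key]], "[[:space:],]+")[[1]]))
    if (any(is.na(v))) stop("config key '", key, "' is not numeric")
    v
  }
  type <- tolower(kv$type)
  if (type == "coms16") {
    coms16_plaque(eye,
                  ring_radii = nums("ring_radii", c(3.0, 5.8)),
                  ring_counts = as.integer(nums("ring_counts", c(4, 8))),
                  ring_phases = nums("ring_phases", c(0, 22.5)),
                  central = !identical(kv$central, "false"),
                  seed_center_depth = nums("seed_center_depth", 2.75),
                  diameter = nums("diameter", 16))
  } else if (type == "nag16") {
    nag16_plaque(eye,
                 inner_half_diagonal = nums("inner_half_diagonal", 3.0),
                 outer_half_diagonal = nums("outer_half_diagonal", 5.5),
                 inner_phase = nums("inner_phase", 0),
                 seed_center_depth = nums("seed_center_depth", 1.4),
                 diameter = nums("diameter", 16))
  } else {
    stop("unknown plaque type '", kv$type, "' (expected coms16 or nag16)")
  }
}
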