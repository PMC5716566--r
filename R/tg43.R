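#' TG-43 line-source geometry factor
#'
#' Evaluates the line-source geometry factor
#' G_L(r, theta) = beta / (L * r * sin(theta)), with beta the angle (radians)
#' subtended at the point by the active segment of length `L` centred on the
#' origin and aligned with the polar axis.  On the seed long axis
#' (theta = 0 or 180 deg) the closed form 1 / (r^2 - L^2/4) applies; with
#' `L = 0` the point-source limit 1 / r^2 is returned.
#'
#' @param r Distance(s) from the seed centre in cm, > 0.
#' @param theta Polar angle(s) from the seed long axis in degrees, \[0, 180\].
#' @param L Active length in cm (0 for point-source mode).
#' @return Geometry factor in 1/cm^2, same length as `r`.
#' @export
#' @examples
#' geometry_factor(1, 90, 0)            # 1 (point source at 1 cm)
#' geometry_factor(1, 90, 0.3)          # slightly below 1
geometry_factor <- function(r, theta, L) {
  stopifnot(length(L) == 1L, is.finite(L), L >= 0)
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n)
  theta <- rep_len(as.numeric(theta), n)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("geometry_factor requires r > 0")
  if (any(theta < 0 | theta > 180))
    stop("theta must lie in [0, 180] degrees")
  if (L == 0) return(1 / r^2)
  th <- theta * pi / 180
  x <- r * sin(th)          # transverse offset from the seed axis
  z <- r * cos(th)          # position along the seed axis
  eps <- 1e-12
  on_axis <- x <= eps
  if (any(on_axis & abs(z) <= L / 2 + eps & abs(abs(z) - L / 2) <= eps))
    stop("point lies on the tip of the active segment: geometry undefined")
  if (any(on_axis & abs(z) < L / 2))
    stop("point lies inside the active segment (r*sin(theta) = 0, |r*cos(theta)| < L/2): geometry undefined")
  g <- numeric(n)
  if (any(on_axis))
    g[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  off <- !on_axis
  if (any(off)) {
    beta <- atan2(L / 2 - z[off], x[off]) - atan2(-L / 2 - z[off], x[off])
    g[off] <- beta / (L * x[off])
  }
  g
}

#' Interpolate a radial dose function
#'
#' Log-linear interpolation of g(r): linear in log(g) against r, exact at the
#' table nodes.  Below the first node the first value is clamped (no
#' extrapolation into the capsule region); beyond the last node the last
#' log-linear segment is extended.
#'
#' @param table A [radial_dose_table()].
#' @param r Radial distance(s) in cm, > 0.
#' @return Dimensionless g(r), same length as `r`.
#' @export
interp_radial <- function(table, r) {
  stopifnot(inherits(table, "radial_dose_table"))
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("interp_radial requires r > 0")
  rr <- table$radii
  lv <- log(table$values)
  nn <- length(rr)
  lg <- stats::approx(rr, lv, xout = pmin(pmax(r, rr[1]), rr[nn]))$y
  hi <- r > rr[nn]
  if (any(hi)) {
    slope <- (lv[nn] - lv[nn - 1]) / (rr[nn] - rr[nn - 1])
    lg[hi] <- lv[nn] + slope * (r[hi] - rr[nn])
  }
  out <- exp(lg)
  # exact (bit-identical) values at the table nodes
  at_node <- match(r, rr)
  hit <- !is.na(at_node)
  out[hit] <- table$values[at_node[hit]]
  out
}

#' Interpolate an anisotropy function
#'
#' Bilinear interpolation of F(r, theta) on its rectangular grid.  Angles
#' above 90 degrees are mapped to 180 - theta (seed mirror symmetry); radii
#' and angles outside the grid are clamped to the nearest grid line.  The
#' constant-1 sentinel returns 1 everywhere.
#'
#' @param table An [anisotropy_table()] or [anisotropy_sentinel()].
#' @param r Radial distance(s) in cm, > 0.
#' @param theta Polar angle(s) in degrees, \[0, 180\].
#' @return Dimensionless F(r, theta).
#' @export
interp_anisotropy <- function(table, r, theta) {
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n)
  theta <- rep_len(as.numeric(theta), n)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("interp_anisotropy requires r > 0")
  if (any(theta < 0 | theta > 180))
    stop("theta must lie in [0, 180] degrees")
  if (inherits(table, "anisotropy_sentinel")) return(rep(1, n))
  stopifnot(inherits(table, "anisotropy_table"))
  th <- ifelse(theta > 90, 180 - theta, theta)
  rr <- table$radii
  aa <- table$angles
  rc <- pmin(pmax(r, rr[1]), rr[length(rr)])
  tc <- pmin(pmax(th, aa[1]), aa[length(aa)])
  i <- findInterval(rc, rr, rightmost.closed = TRUE, all.inside = TRUE)
  j <- findInterval(tc, aa, rightmost.closed = TRUE, all.inside = TRUE)
  fr <- (rc - rr[i]) / (rr[i + 1] - rr[i])
  fa <- (tc - aa[j]) / (aa[j + 1] - aa[j])
  v <- table$values
  (1 - fr) * (1 - fa) * v[cbind(i, j)] +
    fr * (1 - fa) * v[cbind(i + 1, j)] +
    (1 - fr) * fa * v[cbind(i, j + 1)] +
    fr * fa * v[cbind(i + 1, j + 1)]
}

#' Single-seed dose rate per unit air-kerma strength
#'
#' TG-43U1 2D formalism:
#' dose rate = Lambda * G_L(r, theta) / G_L(1 cm, 90 deg) * g(r) * F(r, theta),
#' in cGy/(h*U).  At (1 cm, 90 deg) this equals the dose-rate constant by
#' construction.
#'
#' @param model A [source_model()].
#' @param r Distance(s) from the seed centre in cm.
#' @param theta Polar angle(s) from the seed long axis in degrees.
#' @return Dose rate(s) in cGy/(h*U).
#' @export
#' @examples
#' iai <- load_source_model("IAI-125A")
#' dose_rate_single(iai, 1, 90)   # = 0.979, the dose-rate constant
dose_rate_single <- function(model, r, theta) {
  stopifnot(inherits(model, "source_model"))
  L <- model$active_length
  gl <- if (L == 0) 1 / rep_len(as.numeric(r), max(length(r), length(theta)))^2
        else geometry_factor(r, theta, L) / geometry_factor(1, 90, L)
  model$dose_rate_constant * gl *
    interp_radial(model$radial, r) *
    interp_anisotropy(model$anisotropy, r, theta)
}

#' Effective irradiation time of a decaying implant
#'
#' For a seed of half-life T (days) left in place for a finite duration
#' (days), the delivered dose equals the initial dose rate multiplied by
#' tau = (T / ln 2) * (1 - 2^(-duration / T)), returned here in hours.
#' `duration = Inf` gives the full-decay value 24 * T / ln 2.
#'
#' Air-kerma strengths are quoted at implant time (initial-strength
#' convention).
#'
#' @param half_life Half-life in days, > 0.
#' @param duration Implant duration in days, > 0 (may be `Inf`).
#' @return Effective time tau in hours.
#' @export
#' @examples
#' decay_integral(59.4, 6)     # about 139.1 h for a six-day I-125 implant
#' decay_integral(9.689, 6)    # about 117.1 h for Cs-131
decay_integral <- function(half_life, duration) {
  if (any(!is.finite(half_life)) || any(half_life <= 0))
    stop("half_life must be positive")
  if (any(is.na(duration)) || any(duration <= 0))
    stop("duration must be positive")
  24 * (half_life / log(2)) * (1 - 2^(-duration / half_life))
}
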