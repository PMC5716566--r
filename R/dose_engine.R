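#' Superpose single-seed dose rates over a plaque
#'
#' Evaluates the TG-43 dose rate per unit per-seed air-kerma strength at
#' arbitrary points by summing [dose_rate_single()] over all seeds, each
#' evaluated in its own seed frame (distance and polar angle derived from the
#' seed centre and long-axis orientation).  All seeds are assumed to carry
#' equal strength.
#'
#' @param plaque A `plaque_model` ([coms16_plaque()], [nag16_plaque()], ...).
#' @param model A [source_model()].
#' @param points n x 3 matrix of evaluation points in mm (eye frame); a
#'   single point may be a length-3 vector.
#' @return An object of class `dose_map`: list with `points` (mm), `values`
#'   and `tag = "rate"` (units cGy/(h*U) of per-seed strength).
#' @export
#' @examples
#' plq <- coms16_plaque()
#' superpose(plq, load_source_model("IAI-125A"), c(0, 0, 6))
superpose <- function(plaque, model, points) {
  stopifnot(inherits(plaque, "plaque_model"), inherits(model, "source_model"))
  p <- .as_points(points) / 10            # mm -> cm
  vals <- numeric(nrow(p))
  L <- model$active_length
  for (i in seq_len(plaque$n_seeds)) {
    d <- sweep(p, 2, plaque$seeds[i, ])
    r <- sqrt(rowSums(d^2))
    if (any(r < 1e-12))
      stop("evaluation point coincides with the centre of seed ", i)
    ct <- pmin(1, pmax(-1, as.vector(d %*% plaque$orientations[i, ]) / r))
    if (L > 0) {
      trans <- r * sqrt(pmax(0, 1 - ct^2))
      if (any(trans <= 1e-12 & abs(r * ct) < L / 2))
        stop("evaluation point lies inside the active segment of seed ", i)
    }
    vals <- vals + dose_rate_single(model, r, acos(ct) * 180 / pi)
  }
  structure(list(points = .as_points(points), values = vals,
                 tag = "rate", unit = "cGy/(h U)",
                 plaque = plaque$name, model = model$name),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("Dose map: %d points, %s [%s] (%s / %s)\n", nrow(x$points),
              if (x$tag == "rate") "dose rate per unit per-seed strength"
              else "absolute dose", x$unit,
              x$plaque %||% "?", x$model %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Axial grid of the standard comparison table
#'
#' Z positions (mm from the inner sclera) used for the central-axis dose
#' comparison: -1 mm (outer sclera) to 10 mm in 1 mm steps, then 12 mm to
#' 30 mm in 2 mm steps.
#'
#' @return Numeric vector of Z values in mm.
#' @export
default_axis_grid <- function() c(-1, 0:10, seq(12, 30, by = 2))

#' Central-axis dose profile
#'
#' Evaluates [superpose()] on points (0, 0, Z) along the plaque central axis.
#'
#' @inheritParams superpose
#' @param z_mm Z positions in mm (default [default_axis_grid()]).
#' @return A `dose_map` with an extra `z_mm` field.
#' @export
central_axis_profile <- function(plaque, model, z_mm = default_axis_grid()) {
  m <- superpose(plaque, model, cbind(0, 0, as.numeric(z_mm)))
  m$z_mm <- as.numeric(z_mm)
  m
}

#' Pointwise ratio of two dose maps
#'
#' @param p1,p2 `dose_map`s evaluated on the same point grid.
#' @return Numeric vector of `p1$values / p2$values`.
#' @export
profile_ratio <- function(p1, p2) {
  stopifnot(inherits(p1, "dose_map"), inherits(p2, "dose_map"))
  if (!isTRUE(all.equal(p1$points, p2$points, check.attributes = FALSE)))
    stop("dose maps are not on the same point grid")
  if (any(p2$values == 0)) stop("zero denominator in profile ratio")
  p1$values / p2$values
}
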