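#' Build the spherical tally lattice over a region
#'
#' Places non-overlapping spherical tally cells (default 1 mm diameter) on a
#' cubic grid (default 1 mm spacing) restricted to a region: the x and y
#' coordinates run over integer multiples of the spacing and the z planes are
#' offset by `offset` (default half a spacing, so one cell centre sits on the
#' axis at Z = 0.5 mm and no centre falls exactly on the Z = 0 boundary).
#' Cell ordering is lexicographic by Z, then Y, then X, so lattice
#' construction is deterministic.
#'
#' For dose-volume bookkeeping each cell represents its grid voxel, i.e. a
#' volume of `spacing^3` (1 mm^3 by default): the cumulative volume fraction
#' at a dose level is then simply the fraction of cells at or above it.  The
#' sphere radius is the physical tally-cell size and enforces the
#' non-overlap constraint `radius <= spacing / 2`.
#'
#' @param region A `tumor_model` or `eye_model` (see [region_contains()]).
#' @param spacing Grid spacing in mm (default 1).
#' @param radius Tally sphere radius in mm (default 0.5).
#' @param offset Z offset of the first grid plane in mm (default
#'   `spacing / 2`).
#' @return An object of class `tally_lattice`: `centers` (n x 3 mm, may have
#'   zero rows for an empty region), `spacing`, `radius`, `cell_volume_mm3`.
#' @export
#' @examples
#' lat <- build_lattice(make_tumor(make_eye()))
#' nrow(lat$centers)
build_lattice <- function(region, spacing = 1, radius = 0.5,
                          offset = spacing / 2) {
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (radius > spacing / 2)
    stop("radius > spacing/2: tally spheres would overlap")
  if (inherits(region, "tumor_model")) {
    xmax <- region$a; ymax <- region$b; zmin <- 0; zmax <- region$h
  } else if (inherits(region, "eye_model")) {
    xmax <- region$inner_radius; ymax <- region$inner_radius
    zmin <- 0; zmax <- 2 * region$inner_radius
  } else stop("region must be a tumor_model or eye_model")
  xs <- spacing * seq(-ceiling(xmax / spacing), ceiling(xmax / spacing))
  ys <- spacing * seq(-ceiling(ymax / spacing), ceiling(ymax / spacing))
  zs <- offset + spacing * seq(floor((zmin - offset) / spacing),
                               ceiling((zmax - offset) / spacing))
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g[order(g$z, g$y, g$x), , drop = FALSE])
  keep <- region_contains(region, g)
  centers <- g[keep, , drop = FALSE]
  rownames(centers) <- NULL
  structure(list(centers = centers, spacing = spacing, radius = radius,
                 cell_volume_mm3 = spacing^3,
                 region = class(region)[1]),
            class = "tally_lattice")
}

#' Cumulative dose-volume histogram on a tally lattice
#'
#' Computes the cumulative DVH of an absolute-dose map sampled at the
#' lattice cell centres: equal-volume cells, cumulative volume fraction at
#' dose d = (number of cells with dose >= d) / N * 100.  Also evaluates the
#' standard summary metrics V100/V125/V150/V200 (percent of the region
#' receiving at least that percentage of the prescription dose) and D0.1cc.
#'
#' @param lattice A [build_lattice()] result.
#' @param dose A `dose_map` with `tag = "absolute"` evaluated exactly at
#'   `lattice$centers`.
#' @param rx The [prescription_spec()] defining 100%.
#' @return An object of class `dvh_result`: sorted cell doses, `cell_volume`
#'   (cm^3), `dose_axis` / `volume_pct` curve, and a `metrics` list.
#' @export
compute_dvh <- function(lattice, dose, rx = prescription_spec()) {
  stopifnot(inherits(lattice, "tally_lattice"), inherits(dose, "dose_map"),
            inherits(rx, "prescription_spec"))
  if (dose$tag != "absolute")
    stop("compute_dvh needs an absolute-dose map (see absolute_dose())")
  if (nrow(dose$points) != nrow(lattice$centers) ||
      !isTRUE(all.equal(dose$points, lattice$centers,
                        check.attributes = FALSE)))
    stop("dose map was not evaluated at the lattice cell centres")
  d <- sort(dose$values, decreasing = TRUE)
  n <- length(d)
  if (n == 0) stop("empty lattice: no cells to histogram")
  cv <- lattice$cell_volume_mm3 / 1000      # cm^3 per cell
  axis <- seq(0, max(d) * 1.001, length.out = 512)
  vol <- vapply(axis, function(x) 100 * mean(d >= x), numeric(1))
  res <- structure(list(doses = d, n_cells = n, cell_volume = cv,
                        rx_dose = rx$dose, dose_axis = axis,
                        volume_pct = vol),
                   class = "dvh_result")
  res$metrics <- list(V100 = dvh_metric_Vx(res, 100),
                      V125 = dvh_metric_Vx(res, 125),
                      V150 = dvh_metric_Vx(res, 150),
                      V200 = dvh_metric_Vx(res, 200),
                      D0.1cc = dvh_metric_Dv(res, 0.1))
  res
}

#' V_x metric: percent volume receiving at least x% of the prescription
#'
#' @param dvh A [compute_dvh()] result.
#' @param x Dose level as a percentage of the prescription dose.
#' @return Volume percentage in \[0, 100\].
#' @export
dvh_metric_Vx <- function(dvh, x) {
  stopifnot(inherits(dvh, "dvh_result"))
  100 * mean(dvh$doses >= x / 100 * dvh$rx_dose)
}

#' D_v metric: minimum dose to the hottest v cm^3
#'
#' Sorts the cell doses in decreasing order and returns the dose at
#' cumulative volume `v`, with linear interpolation inside the marginal
#' cell.  `v` equal to the full region volume returns the minimum cell dose.
#'
#' @param dvh A [compute_dvh()] result.
#' @param v Volume in cm^3, 0 < v <= region volume.
#' @return Dose in Gy.
#' @export
dvh_metric_Dv <- function(dvh, v) {
  stopifnot(inherits(dvh, "dvh_result"))
  total <- dvh$n_cells * dvh$cell_volume
  if (!is.finite(v) || v <= 0) stop("v must be positive (cm^3)")
  if (v > total + 1e-12)
    stop(sprintf("v = %g cm^3 exceeds the region volume (%g cm^3)", v, total))
  cum <- seq_len(dvh$n_cells) * dvh$cell_volume
  if (v <= cum[1]) return(dvh$doses[1])
  stats::approx(cum, dvh$doses, xout = min(v, total))$y
}

#' @export
print.dvh_result <- function(x, ...) {
  cat(sprintf("DVH over %d cells (%.3f cm^3), prescription %g Gy\n",
              x$n_cells, x$n_cells * x$cell_volume, x$rx_dose))
  m <- x$metrics
  cat(sprintf("  V100 %.1f%%  V125 %.1f%%  V150 %.1f%%  V200 %.1f%%  D0.1cc %.1f Gy\n",
              m$V100, m$V125, m$V150, m$V200, m$D0.1cc))
  invisible(x)
}

#' @export
plot.dvh_result <- function(x, percent_of_rx = FALSE, ...) {
  xs <- if (percent_of_rx) 100 * x$dose_axis / x$rx_dose else x$dose_axis
  graphics::plot(xs, x$volume_pct, type = "l",
                 xlab = if (percent_of_rx) "Dose (% of prescription)" else "Dose (Gy)",
                 ylab = "Volume (%)", ylim = c(0, 100), ...)
  invisible(x)
}
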