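#' Prescription specification
#'
#' The clinical prescription: `dose` Gy delivered at `depth` mm from the
#' inner sclera on the plaque central axis (the tumor apex for the default
#' 6 mm tumor) over an implant of `duration` days.
#'
#' @param dose Prescription dose in Gy (default 85).
#' @param depth Prescription depth in mm from the inner sclera (default 6).
#' @param duration Implant duration in days (default 6).
#' @return An object of class `prescription_spec`.
#' @export
prescription_spec <- function(dose = 85, depth = 6, duration = 6) {
  if (any(!is.finite(c(dose, depth, duration))) ||
      any(c(dose, depth, duration) <= 0))
    stop("dose, depth and duration must all be positive")
  structure(list(dose = dose, depth = depth, duration = duration),
            class = "prescription_spec")
}

#' Solve the per-seed air-kerma strength for a prescription
#'
#' Dose is linear in source strength, so the solution is a single division:
#' per-seed strength = dose / (rate(P) * tau), where rate(P) is the
#' per-unit-strength dose rate at the prescription point (Gy/(h*U), summed
#' over seeds) and tau = [decay_integral()] of the model half-life over the
#' implant duration.  Re-evaluating the implant with the returned strength
#' reproduces the prescription dose at P to machine precision.
#'
#' @param plaque A `plaque_model`.
#' @param model A [source_model()].
#' @param rx A [prescription_spec()].
#' @return An object of class `strength_result` with fields `per_seed` (U),
#'   `total` (U), `n_seeds`, `tau_h`, `plaque`, `model`, `rx`.
#' @export
#' @examples
#' solve_strength(nag16_plaque(), load_source_model("IAI-125A"),
#'                prescription_spec())
solve_strength <- function(plaque, model, rx = prescription_spec()) {
  stopifnot(inherits(rx, "prescription_spec"))
  rate <- superpose(plaque, model, c(0, 0, rx$depth))$values   # cGy/(h U)
  if (rate <= 0) stop("zero dose rate at the prescription point")
  tau <- decay_integral(model$half_life, rx$duration)
  per_seed <- rx$dose / (rate / 100 * tau)
  structure(list(per_seed = per_seed, total = per_seed * plaque$n_seeds,
                 n_seeds = plaque$n_seeds, tau_h = tau,
                 plaque = plaque$name, model = model$name, rx = rx),
            class = "strength_result")
}

#' @export
print.strength_result <- function(x, ...) {
  cat(sprintf("%s / %s: %.3f U/seed (%.2f U total over %d seeds)\n",
              x$plaque, x$model, x$per_seed, x$total, x$n_seeds))
  cat(sprintf("  for %g Gy at %g mm over %g d (tau = %.2f h)\n",
              x$rx$dose, x$rx$depth, x$rx$duration, x$tau_h))
  invisible(x)
}

#' Convert a dose-rate map to absolute dose
#'
#' Multiplies a per-unit-strength dose-rate map by the per-seed air-kerma
#' strength and the effective irradiation time of the implant, yielding
#' absolute dose in Gy.
#'
#' @param map A `dose_map` with `tag = "rate"`.
#' @param strength Per-seed air-kerma strength in U (or a `strength_result`).
#' @param model The [source_model()] (supplies the half-life).
#' @param duration Implant duration in days.
#' @return A `dose_map` with `tag = "absolute"` and values in Gy.
#' @export
absolute_dose <- function(map, strength, model, duration) {
  stopifnot(inherits(map, "dose_map"))
  if (inherits(strength, "strength_result")) strength <- strength$per_seed
  if (map$tag != "rate")
    stop("dose map already holds absolute dose; cannot retag")
  tau <- decay_integral(model$half_life, duration)
  map$values <- map$values / 100 * strength * tau
  map$tag <- "absolute"
  map$unit <- "Gy"
  map
}
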