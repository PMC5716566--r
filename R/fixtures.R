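# Synthetic fixtures and an independent superposition oracle.  These are
# first-class, exported functions: the analytic toy source gives closed-form
# expectations, random_plaque produces reproducible scattered configurations
# and oracle_superpose is a deliberately naive re-implementation of the
# TG-43 sum (scalar loops, its own interpolation code) used to cross-check
# the vectorized engine.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Analytic inverse-square toy source
#'
#' A point source with dose-rate constant 1, g(r) = 1 and F = 1, so that the
#' dose rate is exactly 1/r^2 cGy/(h*U) everywhere.  Used for closed-form
#' tests of the engine, the prescription solver and the DVH pipeline.
#'
#' @param half_life Half-life in days (default 60).
#' @return A [source_model()] named `"TOY"` in point-source mode.
#' @export
#' @examples
#' dose_rate_single(make_toy_source(), 2, 37)   # 0.25
make_toy_source <- function(half_life = 60) {
  source_model(name = "TOY", dose_rate_constant = 1, active_length = 0,
               physical_length = 0.45, half_life = half_life,
               radial = radial_dose_table(c(0.1, 1, 10), c(1, 1, 1)))
}

#' Random plaque fixture
#'
#' Scatters `n_seeds` seed centres uniformly over a spherical cap behind the
#' inner sclera, with tangential (azimuthal) orientations.  Fully
#' deterministic given `seed_value`; the caller's RNG state is preserved.
#'
#' @param n_seeds Number of seeds, >= 1.
#' @param seed_value Integer RNG seed.
#' @param eye An [make_eye()] model.
#' @param cap_half_angle Half-angle of the cap about the plaque pole, degrees.
#' @param seed_center_depth Depth of seed centres behind the inner sclera, mm.
#' @return A `plaque_model` named `"RANDOM-<n>"`.
#' @export
random_plaque <- function(n_seeds, seed_value, eye = make_eye(),
                          cap_half_angle = 30, seed_center_depth = 2) {
  stopifnot(n_seeds >= 1)
  Rs <- eye$inner_radius + seed_center_depth
  .with_seed(seed_value, {
    u <- stats::runif(n_seeds)
    phi <- stats::runif(n_seeds, 0, 2 * pi)
    # uniform over the cap: cos(alpha) uniform on [cos(cap), 1]
    ca <- 1 - u * (1 - cos(cap_half_angle * pi / 180))
    sa <- sqrt(1 - ca^2)
    pos <- cbind(Rs * sa * cos(phi), Rs * sa * sin(phi),
                 eye$center_z - Rs * ca) / 10
    ori <- cbind(-sin(phi), cos(phi), rep(0, n_seeds))
    .plaque_model(paste0("RANDOM-", n_seeds), 2 * Rs *
                    sin(cap_half_angle * pi / 180), pos, ori,
                  seed_center_depth, eye)
  })
}

#' Naive reference superposition (test oracle)
#'
#' Independent scalar re-implementation of the TG-43 line-source sum, sharing
#' no helpers with [superpose()]: the subtended angle comes from the law of
#' cosines on the distances to the two segment ends, and the radial dose
#' function is re-interpolated from scratch in log space.  Intended for
#' cross-checks in tests, not for production use.
#'
#' @inheritParams superpose
#' @return A `dose_map` (empty point list gives an empty map).
#' @export
oracle_superpose <- function(plaque, model, points) {
  p_all <- .as_points(points)
  L <- model$active_length
  tab_r <- model$radial$radii
  tab_g <- model$radial$values
  interp_g <- function(r) {
    if (r <= tab_r[1]) return(tab_g[1])
    n <- length(tab_r)
    if (r >= tab_r[n]) {
      i <- n - 1
    } else {
      i <- max(which(tab_r <= r))
      if (tab_r[i] == r) return(tab_g[i])
    }
    w <- (r - tab_r[i]) / (tab_r[i + 1] - tab_r[i])
    exp((1 - w) * log(tab_g[i]) + w * log(tab_g[i + 1]))
  }
  gl0 <- if (L == 0) 1 else 2 * atan(L / 2) / L    # G_L(1 cm, 90 deg)
  out <- numeric(nrow(p_all))
  for (i in seq_len(nrow(p_all))) {
    p <- p_all[i, ] / 10
    s <- 0
    for (j in seq_len(plaque$n_seeds)) {
      cen <- plaque$seeds[j, ]
      u <- plaque$orientations[j, ]
      v <- p - cen
      r <- sqrt(sum(v * v))
      if (L == 0) {
        gl_ratio <- (1 / r^2) / gl0
        fval <- 1
        th <- 90
      } else {
        e1 <- cen - (L / 2) * u
        e2 <- cen + (L / 2) * u
        da <- sqrt(sum((p - e1)^2))
        db <- sqrt(sum((p - e2)^2))
        costh <- sum(v * u) / r
        th <- acos(min(1, max(-1, costh))) * 180 / pi
        xoff <- r * sqrt(max(0, 1 - costh^2))
        if (xoff < 1e-12) {
          gl <- 1 / (r^2 - L^2 / 4)
        } else {
          cosbeta <- (da^2 + db^2 - L^2) / (2 * da * db)
          gl <- acos(min(1, max(-1, cosbeta))) / (L * xoff)
        }
        gl_ratio <- gl / gl0
        fval <- interp_anisotropy(model$anisotropy, r, th)
      }
      s <- s + model$dose_rate_constant * gl_ratio * interp_g(r) * fval
    }
    out[i] <- s
  }
  structure(list(points = p_all, values = out, tag = "rate",
                 unit = "cGy/(h U)", plaque = plaque$name,
                 model = model$name),
            class = "dose_map")
}
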