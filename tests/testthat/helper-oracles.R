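# Independent numerical oracles used across the test files.  These share no
# code with the package internals they check.

# Line-source geometry factor by brute-force quadrature: average of 1/d^2
# over the active segment, with the seed on the z axis and the point at
# (r sin(theta), 0, r cos(theta)).
quad_geometry_factor <- function(r, theta, L) {
  x <- r * sin(theta * pi / 180)
  z <- r * cos(theta * pi / 180)
  f <- function(l) 1 / (x^2 + (z - l)^2)
  stats::integrate(f, -L / 2, L / 2, rel.tol = 1e-12)$value / L
}

# Effective irradiation time by quadrature of the decay curve (hours).
quad_decay_integral <- function(half_life, duration) {
  24 * stats::integrate(function(t) 2^(-t / half_life), 0, duration,
                        rel.tol = 1e-12)$value
}

# Relative difference helper.
rel_diff <- function(a, b) abs(a - b) / abs(b)

# Standard study objects, built once per test run.
std_eye <- make_eye()
std_rx <- prescription_spec()
std_iai <- load_source_model("IAI-125A")
std_cs <- load_source_model("Cs-1")
std_nag <- nag16_plaque(std_eye)
std_coms <- coms16_plaque(std_eye)
std_combos <- list(list(plaque = std_nag, model = std_iai),
                   list(plaque = std_coms, model = std_iai),
                   list(plaque = std_nag, model = std_cs),
                   list(plaque = std_coms, model = std_cs))
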