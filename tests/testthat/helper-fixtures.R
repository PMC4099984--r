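# Shared test geometries, built in code.

# single-sphere scene: one organ inside a spherical envelope
sphere_scene <- function(r = 10, mass = NULL, material = "soft_tissue") {
  sc <- build_reference_scene("minimal_test")
  sc$organs <- list(fetodose:::.organ(
    1, "ball", "ball", fetodose:::.sph(c(0, 0, 0), r),
    if (is.null(mass)) 4 / 3 * pi * r^3 / 1000 * 1.05 else mass, material,
    source = TRUE))
  sc$envelope$shape <- fetodose:::.sph(c(0, 0, 0), r + 30)
  sc
}

# grid-aligned box scene for exact-count checks
box_scene <- function(half = c(5, 5, 5)) {
  sc <- build_reference_scene("minimal_test")
  sc$organs <- list(fetodose:::.organ(
    1, "box", "box", primitive("box", c(0, 0, 0), half = half),
    1.0, "soft_tissue", source = TRUE))
  sc$envelope$shape <- fetodose:::.sph(c(0, 0, 0), max(half) + 20)
  sc
}

# solid block lattice with a wall-free organ label 1 in an air background
block_lattice <- function(n = 10, spacing = 1, material = "water") {
  lat <- uniform_lattice(c(n + 4, n + 4, n + 4), spacing, "air")
  lat$labels[] <- 0L
  lat$labels[3:(n + 2), 3:(n + 2), 3:(n + 2)] <- 1L
  mats <- material_table()
  lat$label_table <- data.frame(
    label = c(0L, 1L), name = c("air/outside", "block"),
    region = c("air", "block"), material = c("air", material),
    density = c(fetodose:::material_density(mats, "air"),
                fetodose:::material_density(mats, material)),
    target_mass = NA_real_, source = c(FALSE, TRUE), fetal = FALSE,
    stringsAsFactors = FALSE)
  lat
}

# two-compartment chain used by the biokinetics oracle tests
chain_model <- function(k = 2, k2 = 1, lambda = 24 * log(2) / 192.608) {
  compartment_model(
    c("A", "B", "C"),
    data.frame(from = c("A", "B"), to = c("B", "C"), rate = c(k, k2)),
    lambda, c(A = 1),
    region_map = c(A = "A", B = "B", C = "C"), excreta = "C")
}

# independent ODE oracle: cumulated activities by numeric integration of the
# activity ODE with appended cumulative integrals
ode_cumulated_oracle <- function(model, horizon_halflives = 60) {
  n <- length(model$compartments)
  M <- (model$K - diag(model$lambda_phys, n)) / 24   # per hour
  f <- function(t, y, p) list(c(M %*% y[1:n], y[1:n]))
  horizon <- horizon_halflives * 24 * log(2) / model$lambda_phys
  out <- deSolve::lsoda(c(model$A0, numeric(n)), c(0, horizon), f, NULL,
                        rtol = 1e-11, atol = 1e-14)
  setNames(as.numeric(out[2, (n + 2):(2 * n + 1)]), model$compartments)
}
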