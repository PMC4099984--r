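# Tissue materials: density (g/cm^3), elemental mass fractions, and the
# cross-section class used by the transport stage.
#
# Densities follow the usual reference-phantom conventions: ICRP 110 adult
# soft tissues around 1.05 g/cm^3, fetal soft tissue 1.04 (38-week surrogate),
# fetal skeleton 1.22 (mineralising bone, well below adult cortical bone),
# gastrointestinal contents near water. Compositions are standard 9-element
# soft-tissue style mixtures; they feed the documentation and the material
# bookkeeping, while photon interaction data are looked up per `xs_class`.

.material_defs <- function() {
  st <- c(H = 0.102, C = 0.143, N = 0.034, O = 0.708, Na = 0.002,
          P = 0.003, S = 0.003, Cl = 0.002, K = 0.003)
  wat <- c(H = 0.1119, O = 0.8881)
  air <- c(C = 0.000124, N = 0.755268, O = 0.231781, Ar = 0.012827)
  bone <- c(H = 0.064, C = 0.278, N = 0.027, O = 0.410, Mg = 0.002,
            P = 0.070, S = 0.002, Ca = 0.147)
  gi <- c(H = 0.10, C = 0.116, N = 0.022, O = 0.751, Na = 0.001,
          P = 0.001, S = 0.001, Cl = 0.001, K = 0.007)
  list(
    air             = list(density = 0.001205, frac = air,  xs_class = "air"),
    water           = list(density = 1.000,    frac = wat,  xs_class = "water"),
    soft_tissue     = list(density = 1.050,    frac = st,   xs_class = "soft"),
    fetal_soft      = list(density = 1.040,    frac = st,   xs_class = "soft"),
    brain           = list(density = 1.040,    frac = st,   xs_class = "soft"),
    skin            = list(density = 1.090,    frac = st,   xs_class = "soft"),
    lung            = list(density = 0.382,    frac = st,   xs_class = "lung"),
    fetal_lung      = list(density = 1.040,    frac = st,   xs_class = "soft"),
    skeleton        = list(density = 1.300,    frac = bone, xs_class = "bone"),
    fetal_skeleton  = list(density = 1.220,    frac = bone, xs_class = "bone"),
    gi_contents     = list(density = 1.040,    frac = gi,   xs_class = "soft"),
    urine           = list(density = 1.040,    frac = wat,  xs_class = "water"),
    blood           = list(density = 1.060,    frac = st,   xs_class = "soft"),
    placenta        = list(density = 1.020,    frac = st,   xs_class = "soft"),
    amniotic_fluid  = list(density = 1.010,    frac = wat,  xs_class = "water")
  )
}

#' Material table for a phantom profile
#'
#' Returns the material specifications (density in g/cm^3, elemental mass
#' fractions summing to 1, cross-section class) used by a scene profile.
#' Every material referenced by an organ in \code{\link{build_reference_scene}}
#' resolves against this table.
#'
#' @param profile scene profile keyword, \code{"reference_9mo"} or
#'   \code{"minimal_test"} (both use the full table).
#' @return data.frame-like list of \code{MaterialSpec} entries, class
#'   \code{"material_table"}: one element per material with fields
#'   \code{material_id}, \code{density}, \code{elemental_fractions},
#'   \code{xs_class}.
#' @export
material_table <- function(profile = "reference_9mo") {
  defs <- .material_defs()
  out <- lapply(names(defs), function(id) {
    d <- defs[[id]]
    fr <- d$frac / sum(d$frac)  # normalize away rounding in the listed values
    list(material_id = id, density = d$density,
         elemental_fractions = fr, xs_class = d$xs_class)
  })
  names(out) <- names(defs)
  class(out) <- "material_table"
  out
}

#' @export
print.material_table <- function(x, ...) {
  cat("Material table:", length(x), "materials\n")
  for (m in x) {
    cat(sprintf("  %-15s rho = %8.6g g/cm^3  xs = %-6s elements: %s\n",
                m$material_id, m$density, m$xs_class,
                paste(names(m$elemental_fractions), collapse = ",")))
  }
  invisible(x)
}

material_density <- function(materials, id) {
  m <- materials[[id]]
  if (is.null(m)) stop("unknown material: ", id)
  m$density
}

# density vector indexed by label, given label -> material map
label_density <- function(label_table, materials) {
  vapply(label_table$material, function(id) material_density(materials, id),
         numeric(1))
}
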