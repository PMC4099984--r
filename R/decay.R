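# decay_data: radionuclide emission inventories.
#
# Schemes ship as plain-text CSV fixtures (one per nuclide) carrying photon
# and electron lines, beta branches and the half-life. Spectrum policies:
# a yield cutoff (default 0.1% per line), Auger electron groups represented
# at their average energy, conversion electrons at the maximum energy within
# each subshell, and beta continua from the nonrelativistic Coulomb Fermi
# shape against the branch maximum energy.

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "fetodose")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)
  if (!file.exists(p)) stop("fixture not found: ", file)
  p
}

.decay_file <- function(nuclide) {
  switch(nuclide,
         "I-131" = "decay_I-131.csv",
         "I-123" = "decay_I-123.csv",
         "Tc-99m" = "decay_Tc-99m.csv",
         stop("unknown nuclide: ", nuclide))
}

#' Load a radionuclide decay scheme
#'
#' Reads the packaged emission-line fixture for the nuclide. Energies are MeV,
#' yields are emissions per decay; provenance is documented in the fixture
#' header itself.
#'
#' @param nuclide \code{"I-131"}, \code{"I-123"} or \code{"Tc-99m"}.
#' @return object of class \code{decay_scheme} with fields \code{nuclide},
#'   \code{half_life} (hours), \code{lines} (data.frame: particle, origin,
#'   energy, yield, tag), \code{betas} (data.frame: E_max, yield, Z_daughter,
#'   sign), \code{cutoff_applied}.
#' @export
load_scheme <- function(nuclide) {
  path <- .extdata(.decay_file(nuclide))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  hl <- df$energy_MeV[df$type == "half_life"]
  if (length(hl) != 1 || hl <= 0) stop("bad half-life record in ", path)
  ln <- df[df$type == "line", ]
  lines <- data.frame(particle = ln$particle, origin = ln$origin,
                      energy = ln$energy_MeV, yield = ln$yield,
                      tag = ln$tag, stringsAsFactors = FALSE)
  bb <- df[df$type == "beta", ]
  betas <- data.frame(E_max = bb$energy_MeV, yield = bb$yield,
                      Z_daughter = bb$z_daughter,
                      sign = bb$origin, stringsAsFactors = FALSE)
  stopifnot(all(lines$energy > 0), all(lines$yield > 0),
            all(betas$E_max > 0), all(betas$yield > 0), all(betas$yield <= 1))
  structure(list(nuclide = nuclide, half_life = hl, lines = lines,
                 betas = betas, cutoff_applied = FALSE, fixture = path),
            class = "decay_scheme")
}

#' @export
print.decay_scheme <- function(x, ...) {
  cat(sprintf("decay_scheme %s: T1/2 = %.4g h, %d lines (%d photon, %d electron), %d beta branches%s\n",
              x$nuclide, x$half_life, nrow(x$lines),
              sum(x$lines$particle == "photon"),
              sum(x$lines$particle == "electron"), nrow(x$betas),
              if (x$cutoff_applied) ", cutoff applied" else ""))
  invisible(x)
}

#' Half-life in hours for a supported nuclide
#' @param nuclide nuclide name.
#' @export
nuclide_half_life_hours <- function(nuclide) load_scheme(nuclide)$half_life

#' MD5 checksum of a nuclide's decay fixture
#'
#' Guards against silent edits of the packaged line lists.
#' @param nuclide nuclide name.
#' @export
scheme_checksum <- function(nuclide)
  unname(tools::md5sum(.extdata(.decay_file(nuclide))))

#' Remove low-yield emissions
#'
#' Drops lines and beta branches with yield at or below the threshold
#' (default 0.1\% per decay, applied per line). The total removed yield is
#' recorded in the \code{removed_yield} attribute.
#'
#' @param scheme a \code{decay_scheme}.
#' @param threshold yield threshold in emissions per decay, in [0, 1).
#' @return the filtered \code{decay_scheme} with \code{cutoff_applied = TRUE}.
#' @export
apply_yield_cutoff <- function(scheme, threshold = 0.001) {
  stopifnot(threshold >= 0, threshold < 1)
  if (threshold == 0) return(scheme)
  removed <- sum(scheme$lines$yield[scheme$lines$yield <= threshold]) +
    sum(scheme$betas$yield[scheme$betas$yield <= threshold])
  scheme$lines <- scheme$lines[scheme$lines$yield > threshold, ]
  scheme$betas <- scheme$betas[scheme$betas$yield > threshold, ]
  scheme$cutoff_applied <- TRUE
  attr(scheme, "removed_yield") <- removed
  scheme
}

#' Collapse Auger groups and conversion-electron subshells
#'
#' Applies the electron-line policies: each Auger group (rows sharing a
#' \code{tag} ending in \code{"auger"}) becomes one line at the group's
#' yield-weighted average energy carrying the group yield; conversion
#' electrons become one line per subshell tag at the maximum energy within
#' the subshell with the subshell's total yield. Idempotent; total yield is
#' conserved per group, and the change in mean electron energy per decay is
#' recorded in the \code{energy_shift} attribute.
#'
#' @param scheme a \code{decay_scheme}.
#' @return the collapsed \code{decay_scheme}.
#' @export
collapse_electron_lines <- function(scheme) {
  ln <- scheme$lines
  el <- ln$particle == "electron"
  keep <- ln[!el, ]
  eln <- ln[el, ]
  out <- list()
  if (nrow(eln)) {
    for (tg in unique(eln$tag)) {
      g <- eln[eln$tag == tg, ]
      if (g$origin[1] == "auger") {
        e <- sum(g$energy * g$yield) / sum(g$yield)
      } else if (g$origin[1] == "conversion") {
        e <- max(g$energy)
      } else {                      # other electrons: keep as-is
        out[[length(out) + 1L]] <- g
        next
      }
      out[[length(out) + 1L]] <-
        data.frame(particle = "electron", origin = g$origin[1], energy = e,
                   yield = sum(g$yield), tag = tg, stringsAsFactors = FALSE)
    }
  }
  before <- sum(eln$energy * eln$yield)
  newel <- if (length(out)) do.call(rbind, out) else eln[0, ]
  after <- sum(newel$energy * newel$yield)
  scheme$lines <- rbind(keep, newel)
  rownames(scheme$lines) <- NULL
  attr(scheme, "energy_shift") <- after - before
  scheme
}

#' Fermi-shaped beta spectrum of a branch
#'
#' Bin weights are proportional to \eqn{F(Z, W) \, p \, W \, (E_{max}-E)^2}
#' with the nonrelativistic point-charge Coulomb factor
#' \eqn{F = 2\pi\eta / (1 - e^{-2\pi\eta})}, \eqn{\eta = \pm Z \alpha W / p}
#' (positive for beta-minus), \eqn{W} the total energy and \eqn{p} the
#' momentum in electron-mass units. The histogram is normalized to the branch
#' yield on support \eqn{(0, E_{max})}.
#'
#' @param branch one row of a scheme's \code{betas} (list or data.frame row
#'   with \code{E_max}, \code{yield}, \code{Z_daughter}, \code{sign}).
#' @param n_bins number of bins (>= 10); default 1 keV binning.
#' @return data.frame with \code{energy} (bin midpoints, MeV), \code{width}
#'   and \code{weight} (per decay; sums to the branch yield).
#' @export
beta_spectrum <- function(branch, n_bins = NULL) {
  emax <- branch$E_max
  if (!is.numeric(emax) || emax <= 0) stop("E_max must be positive")
  if (is.null(n_bins)) n_bins <- max(10L, ceiling(emax / 0.001))
  stopifnot(n_bins >= 10)
  edges <- seq(0, emax, length.out = n_bins + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- .beta_shape(mid, emax, branch$Z_daughter,
                   minus = !identical(branch$sign, "beta-plus"))
  w <- w / sum(w) * branch$yield
  data.frame(energy = mid, width = diff(edges), weight = w)
}

.beta_shape <- function(E, emax, Z, minus = TRUE) {
  me <- 0.51099895          # MeV
  alpha <- 1 / 137.035999
  W <- 1 + E / me
  p <- sqrt(pmax(W^2 - 1, 1e-30))
  shape <- p * W * (emax - E)^2
  if (Z > 0) {
    eta <- (if (minus) 1 else -1) * Z * alpha * W / p
    x <- 2 * pi * eta
    fermi <- ifelse(abs(x) < 1e-8, 1, x / (1 - exp(-x)))
    shape <- shape * fermi
  }
  shape
}

#' Mean energy of a beta branch (MeV)
#' @param branch beta branch (see \code{\link{beta_spectrum}}).
#' @param n_bins bins for the underlying spectrum.
#' @export
beta_mean_energy <- function(branch, n_bins = NULL) {
  sp <- beta_spectrum(branch, n_bins)
  sum(sp$energy * sp$weight) / sum(sp$weight)
}

#' Sample energies from a beta spectrum
#' @param branch beta branch.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param n_bins bins for the underlying spectrum.
#' @return numeric vector of energies in MeV.
#' @export
sample_beta <- function(branch, n, seed = 1L, n_bins = NULL) {
  sp <- beta_spectrum(branch, n_bins)
  set.seed(seed)
  i <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$weight)
  sp$energy[i] + runif(n, -0.5, 0.5) * sp$width[i]
}

#' Mean emitted energy per decay of a scheme (MeV)
#'
#' Discrete lines plus the mean energies of the beta continua, weighted by
#' yield.
#' @param scheme a \code{decay_scheme}.
#' @param particle optionally restrict to \code{"photon"} or
#'   \code{"electron"} (betas count as electrons).
#' @export
mean_energy_per_decay <- function(scheme, particle = NULL) {
  ln <- scheme$lines
  if (!is.null(particle)) ln <- ln[ln$particle == particle, ]
  e <- sum(ln$energy * ln$yield)
  if (is.null(particle) || particle == "electron")
    for (i in seq_len(nrow(scheme$betas)))
      e <- e + scheme$betas$yield[i] * beta_mean_energy(scheme$betas[i, ])
  e
}
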