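# transport: R front-end over the C++ voxel Monte Carlo kernels.

#' Transport configuration
#'
#' @param n_histories number of primary histories (>= 1).
#' @param seed master RNG seed; each history uses a counter-derived
#'   substream, so results are reproducible and order-independent.
#' @param electron_mode \code{"local"} (full energy deposited in the emission
#'   voxel) or \code{"csda"} (straight-line continuous-slowing-down kernel).
#' @param photon_cutoff photon energy cutoff in MeV (>= 1 keV); photons
#'   falling below deposit locally.
#' @param rr_threshold Russian-roulette energy threshold in MeV: scattered
#'   photons below it play roulette, surviving with probability
#'   \code{1/rr_weight} and carrying that weight onward. 0 disables (the
#'   default; the energy audit then balances exactly rather than in
#'   expectation).
#' @param rr_weight roulette survival weight multiplier (> 1).
#' @param want_mesh also accumulate a per-voxel energy-deposition mesh tally.
#' @param track_first_flight record the mean distance to first interaction
#'   (diagnostic used by the attenuation-length checks).
#' @return list of class \code{transport_config}.
#' @export
transport_config <- function(n_histories = 10000L, seed = 1L,
                             electron_mode = c("local", "csda"),
                             photon_cutoff = 0.002, rr_threshold = 0,
                             rr_weight = 5, want_mesh = FALSE,
                             track_first_flight = FALSE) {
  stopifnot(n_histories >= 1, photon_cutoff >= 0.001, rr_threshold >= 0,
            rr_weight > 1)
  structure(list(n_histories = as.integer(n_histories), seed = seed,
                 electron_mode = match.arg(electron_mode),
                 photon_cutoff = photon_cutoff, rr_threshold = rr_threshold,
                 rr_weight = rr_weight, want_mesh = want_mesh,
                 track_first_flight = track_first_flight),
            class = "transport_config")
}

# label-indexed lookup vectors (position = label + 1)
.lab_vectors <- function(lattice, xs) {
  lt <- lattice$label_table
  maxlab <- max(lattice$labels)
  mats <- material_table()
  cls <- names(xs$classes)
  lab2mat <- integer(maxlab + 1L)          # default: air
  lab2dens <- rep(material_density(mats, "air"), maxlab + 1L)
  lab2mat[] <- match("air", cls) - 1L
  for (r in seq_len(nrow(lt))) {
    lb <- lt$label[r]
    xc <- mats[[lt$material[r]]]$xs_class
    lab2mat[lb + 1L] <- match(xc, cls) - 1L
    lab2dens[lb + 1L] <- lt$density[r]
  }
  list(lab2mat = lab2mat, lab2dens = lab2dens, classes = cls)
}

# region grouping: group index per label (0-based; -1 = untallied), plus
# region names, masses
.region_groups <- function(lattice) {
  lt <- lattice$label_table
  lt <- lt[lt$label != 0L, ]
  regions <- unique(lt$region)
  maxlab <- max(lattice$labels)
  lab2grp <- rep(-1L, maxlab + 1L)
  lab2grp[lt$label + 1L] <- match(lt$region, regions) - 1L
  cnt <- label_index(lattice)
  mass <- vapply(regions, function(rg) {
    labs <- lt$label[lt$region == rg]
    sum(as.numeric(cnt[as.character(labs)]) *
          lt$density[match(labs, lt$label)], na.rm = TRUE) *
      voxel_volume_cm3(lattice)
  }, numeric(1))
  list(lab2grp = lab2grp, regions = regions, mass = mass)
}

# 0-based linear indices of the voxels of a source region
.source_voxels <- function(lattice, source_region) {
  lt <- lattice$label_table
  if (is.numeric(source_region)) labs <- as.integer(source_region)
  else labs <- lt$label[lt$region %in% source_region]
  if (!length(labs)) stop("unknown source region: ",
                          paste(source_region, collapse = ", "))
  idx <- which(lattice$labels %in% labs) - 1L
  if (!length(idx)) stop("empty source region: ",
                         paste(source_region, collapse = ", "))
  idx
}

.mk_tally <- function(res, grp, source_region, particle, energy, config,
                      lattice) {
  n <- res$n_hist
  mean_e <- res$sum / n                       # MeV per history per region
  var_e <- pmax(res$sum2 / n - mean_e^2, 0)
  se <- sqrt(var_e / n)
  rel <- ifelse(mean_e > 0, pmin(se / mean_e, 1), 0)
  df <- data.frame(source = source_region, target = grp$regions,
                   particle = particle, energy = energy,
                   specific_energy = ifelse(grp$mass > 0, mean_e / grp$mass,
                                            0),  # MeV/g per particle
                   rel_err = rel, histories = n,
                   stringsAsFactors = FALSE)
  out <- list(values = df,
              audit = list(emitted = res$emitted,
                           transferred = res$transferred,
                           escaped = res$escaped,
                           cutoff_deposited = res$cutoff_deposited,
                           rr_killed = res$rr_killed %||% 0),
              first_flight_mean_mm = res$first_flight_mean_mm,
              config = config)
  if (!is.null(res$mesh))
    out$mesh <- mesh_tally_from_energy(lattice, res$mesh)
  class(out) <- "tally_result"
  out
}

#' @export
print.tally_result <- function(x, ...) {
  v <- x$values
  cat(sprintf("tally_result: source '%s', %s @ %.4g MeV, %d histories\n",
              v$source[1], v$particle[1], v$energy[1], v$histories[1]))
  top <- v[order(-v$specific_energy), ][seq_len(min(8, nrow(v))), ]
  for (r in seq_len(nrow(top)))
    cat(sprintf("  %-28s %.4g MeV/g  (rel err %.3f)\n", top$target[r],
                top$specific_energy[r], top$rel_err[r]))
  invisible(x)
}

#' Photon transport with kerma-approximation scoring
#'
#' Runs analog photon histories from a source region: histories start
#' uniformly over the source voxels with isotropic directions; free paths are
#' sampled from the local attenuation; interactions are photoelectric-type
#' absorption or free-electron Compton scattering (Klein-Nishina); energy is
#' scored along every track segment with the track-length kerma estimator
#' \eqn{t \cdot E \cdot (\mu_{en}/\rho) \cdot \rho}, aggregated per target
#' region and divided by the region mass.
#'
#' @param lattice a \code{label_lattice}.
#' @param xs an \code{\link{xs_table}}.
#' @param source_region region name (or label vector) of the source.
#' @param energy photon energy in MeV (within the table range).
#' @param config a \code{\link{transport_config}}.
#' @return a \code{tally_result}: \code{values} data.frame (target region,
#'   specific energy in MeV/g per source particle, MC relative error),
#'   energy-conservation \code{audit}, optional mesh tally.
#' @export
transport_photons <- function(lattice, xs, source_region, energy,
                              config = transport_config()) {
  rng_ok <- energy >= min(.xs_grid) && energy <= max(.xs_grid)
  if (!rng_ok) stop("energy outside cross-section table range")
  lv <- .lab_vectors(lattice, xs)
  grp <- .region_groups(lattice)
  src <- .source_voxels(lattice, source_region)
  ng <- length(xs$classes[[1]]$energy)
  logmu <- vapply(lv$classes, function(cl) log(xs$classes[[cl]]$mu_rho),
                  numeric(ng))
  logmen <- vapply(lv$classes, function(cl) log(xs$classes[[cl]]$mu_en_rho),
                   numeric(ng))
  epg <- vapply(lv$classes, function(cl) xs$classes[[cl]]$electrons_per_g,
                numeric(1))
  res <- .cpp_transport_photons(
    lattice$labels, lattice$dims, lattice$spacing, lv$lab2mat, lv$lab2dens,
    log(xs$classes[[1]]$energy), logmu, logmen, epg,
    grp$lab2grp, length(grp$regions), src, energy,
    config$n_histories, as.numeric(config$seed), config$photon_cutoff,
    config$rr_threshold %||% 0, config$rr_weight %||% 5,
    isTRUE(config$want_mesh), isTRUE(config$track_first_flight))
  .mk_tally(res, grp, .region_name(lattice, source_region), "photon", energy,
            config, lattice)
}

.region_name <- function(lattice, source_region) {
  if (is.character(source_region)) return(source_region[1])
  lt <- lattice$label_table
  paste(unique(lt$region[lt$label %in% source_region]), collapse = "+")
}

#' Electron transport (local deposition or CSDA line kernel)
#'
#' In \code{"local"} mode the full electron energy deposits in the emission
#' voxel, so the source region's self specific energy equals
#' \eqn{E / m_{source}} exactly and disjoint targets receive zero; in
#' \code{"csda"} mode each history spreads its energy uniformly in mass path
#' length along a straight sampled direction over the density-scaled CSDA
#' range. Bremsstrahlung is ignored (a documented bias at these energies).
#'
#' @inheritParams transport_photons
#' @param energy electron energy in MeV.
#' @return a \code{tally_result}.
#' @export
transport_electrons <- function(lattice, xs, source_region, energy,
                                config = transport_config()) {
  grp <- .region_groups(lattice)
  src <- .source_voxels(lattice, source_region)
  if (config$electron_mode == "local") {
    # deterministic: every history deposits E in its own source voxel, and
    # the histories are uniform over source voxels
    srcname <- .region_name(lattice, source_region)
    n <- config$n_histories
    # histories are uniform over source voxels; each deposits E where born
    src_lab <- lattice$labels[src + 1L]
    cnt <- table(grp$lab2grp[src_lab + 1L])       # 0-based group index
    sum_e <- numeric(length(grp$regions))
    sum_e[as.integer(names(cnt)) + 1L] <-
      n * energy * as.numeric(cnt) / length(src)
    res <- list(sum = sum_e, sum2 = sum_e^2 / n, n_hist = n,
                emitted = n * energy, transferred = n * energy,
                escaped = 0, cutoff_deposited = 0,
                first_flight_mean_mm = NA_real_)
    if (isTRUE(config$want_mesh)) {
      mesh <- numeric(prod(lattice$dims))
      mesh[src + 1L] <- n * energy / length(src)
      res$mesh <- mesh
    }
    out <- .mk_tally(res, grp, srcname, "electron", energy, config, lattice)
    out$values$rel_err <- 0        # deterministic kernel
    return(out)
  }
  lv <- .lab_vectors(lattice, xs)
  range_gcm2 <- .loglog(xs$csda_energy, xs$csda_gcm2, energy)
  res <- .cpp_transport_electrons_csda(
    lattice$labels, lattice$dims, lattice$spacing, lv$lab2dens,
    grp$lab2grp, length(grp$regions), src, energy, range_gcm2,
    config$n_histories, as.numeric(config$seed), isTRUE(config$want_mesh))
  .mk_tally(res, grp, .region_name(lattice, source_region), "electron",
            energy, config, lattice)
}

#' Mesh tally container
#'
#' Wraps a per-voxel energy-deposition grid (MeV per source particle)
#' together with the voxel volume and the density grid needed to convert to
#' dose.
#' @param lattice the \code{label_lattice} the energies were scored on.
#' @param energy_vec numeric vector of per-voxel energies (MeV), x fastest.
#' @return object of class \code{mesh_tally} with \code{energy_per_cm3}
#'   (MeV/cm^3 per particle) and \code{density} arrays.
#' @export
mesh_tally_from_energy <- function(lattice, energy_vec) {
  vol <- voxel_volume_cm3(lattice)
  lt <- lattice$label_table
  maxlab <- max(lattice$labels)
  dens_lookup <- rep(NA_real_, maxlab + 1L)
  dens_lookup[lt$label + 1L] <- lt$density
  structure(list(
    dims = lattice$dims, spacing = lattice$spacing, origin = lattice$origin,
    energy_per_cm3 = array(energy_vec / vol, dim = lattice$dims),
    density = array(dens_lookup[lattice$labels + 1L], dim = lattice$dims)),
    class = "mesh_tally")
}

#' Convert a mesh tally to a per-voxel dose grid
#'
#' Dose = energy per volume divided by the voxel density (MeV/g per source
#' particle). Voxels with density at or below \code{mask_below} (air) are
#' masked to \code{NA} rather than divided.
#'
#' @param mesh a \code{mesh_tally}.
#' @param mask_below density threshold in g/cm^3.
#' @return 3-D array of dose in MeV/g per source particle.
#' @export
mesh_dose_map <- function(mesh, mask_below = 0.01) {
  d <- mesh$density
  out <- mesh$energy_per_cm3 / d
  out[is.na(d) | d <= mask_below] <- NA_real_
  out
}

#' Aggregate skeletal-site doses into an active-marrow dose
#'
#' Mass-fraction weighted mean over bone sites, with the active-marrow
#' distribution supplied as a configurable table.
#'
#' @param site_doses named numeric vector of per-site doses.
#' @param fractions data.frame with columns \code{site} and \code{fraction}
#'   (fractions sum to 1); default the packaged table restricted to the
#'   supplied sites and renormalized? No: sites must cover the table's names
#'   present in \code{site_doses}.
#' @return list with \code{per_site} (named contributions) and
#'   \code{aggregate}.
#' @export
marrow_endosteal_dose <- function(site_doses,
                                  fractions = load_marrow_fractions()) {
  if (abs(sum(fractions$fraction) - 1) > 1e-6)
    stop("marrow mass fractions must sum to 1")
  miss <- setdiff(fractions$site[fractions$fraction > 0], names(site_doses))
  if (length(miss)) stop("missing site doses: ", paste(miss, collapse = ", "))
  w <- setNames(fractions$fraction, fractions$site)
  per <- site_doses[names(w)] * w
  list(per_site = per, aggregate = sum(per))
}
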