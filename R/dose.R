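# dose_engine: S-values, organ doses, uptake sweeps, provenance comparisons.

#' Unit constant from (hours x MeV/g per decay) to mGy/MBq
#'
#' 3600 s/h x 1e6 decays/(MBq s) x 1.602176634e-10 Gy per MeV/g x 1e3 mGy/Gy.
#' @export
dose_unit_constant <- function()
  3600 * 1e6 * 1.602176634e-10 * 1e3

#' Canonicalize a source/target region name
#'
#' Joins the naming used by the cumulated-activity tables with the phantom's
#' region names (e.g. \code{"SI"} to \code{"small intestine"},
#' \code{"bladder contents"} to \code{"urinary bladder contents"}).
#' @param x character vector of region names.
#' @return canonical names (lower case).
#' @export
canonical_region <- function(x) {
  y <- tolower(trimws(gsub("\\s+", " ", x)))
  y <- gsub("–|—", "-", y)
  al <- c("si" = "small intestine",
          "si wall" = "small intestine wall",
          "si-wall" = "small intestine wall",
          "si contents" = "small intestine contents",
          "bladder contents" = "urinary bladder contents",
          "bladder wall" = "urinary bladder wall",
          "fetus-thyroid" = "fetus thyroid",
          "fetus, thyroid" = "fetus thyroid",
          "remaining-fetus" = "fetus remainder",
          "remaining fetus" = "fetus remainder",
          "fetus remaining" = "fetus remainder",
          "remainder tissues" = "remaining tissues",
          "remainder" = "remaining tissues",
          "residual tissue" = "remaining tissues",
          "salivary gland" = "salivary glands",
          "kidney" = "kidneys")
  hit <- y %in% names(al)
  y[hit] <- al[y[hit]]
  y
}

#' Source-region label sets of the reference scene
#'
#' The ten source regions used for dosimetry (maternal thyroid, stomach wall
#' plus contents, small-intestine wall plus contents, kidneys, liver, bladder
#' contents, salivary glands, maternal remaining tissues, fetal thyroid and
#' fetal remainder), plus \code{"fetus"} (whole fetus as a uniform source,
#' the comparison scenario used when a reference activity set does not treat
#' the fetal thyroid separately) and \code{"placenta"}.
#'
#' @param scene the \code{phantom_scene} (reference profile).
#' @return named list of integer label vectors.
#' @export
source_region_labels <- function(scene) {
  labs <- vapply(scene$organs, `[[`, integer(1), "label")
  fet <- scene$fetus_labels
  list(
    "thyroid" = 1L,
    "salivary glands" = c(2L, 3L),
    "stomach" = c(4L, 5L),
    "small intestine" = c(6L, 7L),
    "liver" = 8L,
    "kidneys" = c(9L, 10L),
    "urinary bladder contents" = 16L,
    "remaining tissues" = c(scene$envelope$label, 11L, 12L, 13L, 14L, 15L,
                            100L, 101L, 102L, 103L),
    "fetus thyroid" = 122L,
    "fetus remainder" = setdiff(fet, 122L),
    "fetus" = fet,
    "placenta" = 101L
  )
}

# emission runs needed for a scheme: one (particle, energy, yield) row per
# discrete line; each beta branch contributes an electron run at its
# spectrum-mean energy
scheme_runs <- function(scheme) {
  ln <- scheme$lines
  runs <- data.frame(particle = ln$particle, energy = ln$energy,
                     yield = ln$yield, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(scheme$betas)))
    runs <- rbind(runs, data.frame(
      particle = "electron",
      energy = beta_mean_energy(scheme$betas[i, ]),
      yield = scheme$betas$yield[i]))
  runs
}

#' Assemble per-decay S-values from transport tallies
#'
#' \eqn{S(T \leftarrow s) = \sum_{emissions} yield \times D_{pp}(T \leftarrow
#' s)} with \eqn{D_{pp}} the specific energy per source particle (MeV/g) from
#' the tallies; photon and electron components are retained separately and
#' the MC relative error is propagated in quadrature.
#'
#' @param tallies list of \code{tally_result} objects, each carrying the
#'   emission yield to apply as attribute \code{"yield"} (set by
#'   \code{\link{compute_svalues}}), or a list of lists
#'   \code{list(tally =, yield =)}.
#' @param scheme the \code{decay_scheme} the tallies are meant to cover.
#' @return \code{svalue_set}: data.frame with columns \code{source},
#'   \code{target}, \code{S} (MeV/g per decay), \code{S_photon},
#'   \code{S_electron}, \code{rel_err}.
#' @export
assemble_svalues <- function(tallies, scheme) {
  runs <- scheme_runs(scheme)
  items <- lapply(tallies, function(t) {
    if (inherits(t, "tally_result"))
      list(tally = t, yield = attr(t, "yield"))
    else t
  })
  # coverage check: every (particle, energy) of the scheme must be present
  key <- function(p, e) paste(p, signif(e, 8))
  have <- unique(unlist(lapply(items, function(it)
    key(it$tally$values$particle[1], it$tally$values$energy[1]))))
  need <- unique(key(runs$particle, runs$energy))
  gaps <- setdiff(need, have)
  if (length(gaps))
    stop("missing tally coverage for: ", paste(gaps, collapse = "; "))
  rows <- list()
  for (it in items) {
    v <- it$tally$values
    y <- it$yield
    if (is.null(y)) stop("tally without a yield")
    rows[[length(rows) + 1L]] <- data.frame(
      source = v$source, target = v$target, particle = v$particle,
      contrib = y * v$specific_energy,
      err2 = (y * v$specific_energy * v$rel_err)^2,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(source = character(0), target = character(0),
                      S = numeric(0), S_photon = numeric(0),
                      S_electron = numeric(0), rel_err = numeric(0),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("svalue_set", "data.frame"),
                     nuclide = scheme$nuclide))
  }
  df <- do.call(rbind, rows)
  agg <- function(sub) {
    ph <- sum(sub$contrib[sub$particle == "photon"])
    el <- sum(sub$contrib[sub$particle == "electron"])
    s <- ph + el
    data.frame(source = sub$source[1], target = sub$target[1],
               S = s, S_photon = ph, S_electron = el,
               rel_err = if (s > 0) sqrt(sum(sub$err2)) / s else 0,
               stringsAsFactors = FALSE)
  }
  sp <- split(df, paste(df$source, df$target, sep = "\r"))
  out <- do.call(rbind, lapply(sp, agg))
  rownames(out) <- NULL
  structure(out, class = c("svalue_set", "data.frame"), nuclide = scheme$nuclide)
}

#' Run transport for every emission of a scheme and assemble S-values
#'
#' Convenience driver: one photon or electron transport run per discrete line
#' (beta branches at their spectrum-mean energy) per source region, then
#' \code{\link{assemble_svalues}}.
#'
#' @param lattice a \code{label_lattice}.
#' @param xs an \code{\link{xs_table}}.
#' @param scheme a \code{decay_scheme} (apply the yield cutoff and electron
#'   collapse first).
#' @param source_labels named list: source region name -> label vector.
#' @param config a \code{\link{transport_config}}.
#' @return an \code{svalue_set} covering all sources.
#' @export
compute_svalues <- function(lattice, xs, scheme, source_labels,
                            config = transport_config()) {
  runs <- scheme_runs(scheme)
  all <- list()
  for (srcname in names(source_labels)) {
    labs <- source_labels[[srcname]]
    labs <- labs[labs %in% lattice$label_table$label]
    tl <- list()
    for (r in seq_len(nrow(runs))) {
      cfg <- config
      cfg$seed <- as.numeric(config$seed) + 1000 * r
      t <- if (runs$particle[r] == "photon")
        transport_photons(lattice, xs, labs, runs$energy[r], cfg)
      else
        transport_electrons(lattice, xs, labs, runs$energy[r], cfg)
      t$values$source <- srcname
      tl[[r]] <- list(tally = t, yield = runs$yield[r])
    }
    all[[srcname]] <- assemble_svalues(tl, scheme)
  }
  out <- do.call(rbind, all)
  rownames(out) <- NULL
  structure(out, class = c("svalue_set", "data.frame"),
            nuclide = scheme$nuclide)
}

#' Organ doses from S-values and cumulated activities
#'
#' \eqn{D_T = \sum_s \tilde A_s \, C \, S(T \leftarrow s)} in mGy/MBq, with
#' \eqn{C} the exact unit constant (\code{\link{dose_unit_constant}}).
#' Excreta regions (urine, feces) in the activity set are skipped; any other
#' activity region without S-values is an error.
#'
#' @param svalues an \code{svalue_set}.
#' @param activities a \code{cumulated_activity_set} (entries in hours).
#' @return \code{organ_dose_table}: data.frame \code{target}, \code{dose}
#'   (mGy/MBq) with metadata attributes.
#' @export
organ_doses <- function(svalues, activities) {
  C <- dose_unit_constant()
  src_avail <- unique(svalues$source)
  ent <- activities$entries
  names(ent) <- canonical_region(names(ent))
  skip <- intersect(names(ent), c("urine", "feces"))
  ent <- ent[setdiff(names(ent), skip)]
  miss <- setdiff(names(ent), canonical_region(src_avail))
  if (length(miss))
    stop("no S-values for source region(s): ", paste(miss, collapse = ", "))
  targets <- unique(svalues$target)
  dose <- setNames(numeric(length(targets)), targets)
  for (s in names(ent)) {
    rows <- svalues[canonical_region(svalues$source) == s, ]
    dose[rows$target] <- dose[rows$target] + ent[[s]] * C * rows$S
  }
  out <- data.frame(target = names(dose), dose = as.numeric(dose),
                    stringsAsFactors = FALSE)
  attr(out, "nuclide") <- activities$nuclide
  attr(out, "uptake") <- activities$uptake
  attr(out, "provenance") <- activities$provenance
  class(out) <- c("organ_dose_table", "data.frame")
  out
}

#' @export
print.organ_dose_table <- function(x, ...) {
  cat(sprintf("organ_dose_table (%s, uptake %s, activities: %s)\n",
              attr(x, "nuclide") %||% "?",
              if (is.null(attr(x, "uptake")) || is.na(attr(x, "uptake"))) "-"
              else paste0(100 * attr(x, "uptake"), "%"),
              attr(x, "provenance") %||% "?"))
  df <- as.data.frame(x)
  df <- df[order(-df$dose), ]
  for (r in seq_len(min(nrow(df), 12)))
    cat(sprintf("  %-28s %.4g mGy/MBq\n", df$target[r], df$dose[r]))
  if (nrow(df) > 12) cat("  ...\n")
  invisible(x)
}

#' Organ doses across maximum-thyroid-uptake levels
#'
#' Builds the iodide pregnancy model at each uptake level, computes cumulated
#' activities (bladder contents via the voiding model), and combines them
#' with fixed S-values into one dose table per level.
#'
#' @param nuclide \code{"I-131"} or \code{"I-123"}.
#' @param svalues an \code{svalue_set} for this nuclide's scheme on the
#'   phantom.
#' @param levels uptake fractions; default the seven canonical levels.
#' @param constants iodide rate-constant bundle.
#' @param schedule voiding schedule for the bladder contents.
#' @return named list of \code{organ_dose_table}s (names = uptake levels).
#' @export
uptake_sweep <- function(nuclide, svalues, levels = uptake_levels(),
                         constants = iodide_default_constants(),
                         schedule = voiding_schedule()) {
  out <- list()
  for (F in levels) {
    act <- pipeline_activities(nuclide, F, constants, schedule)
    out[[sprintf("%g", F)]] <- organ_doses(svalues, act)
  }
  out
}

#' Computed cumulated activities ready for dosimetry
#'
#' Solves the iodide pregnancy model and replaces the urine-sink entry by the
#' voiding-bladder cumulated activity (reported as \code{"urinary bladder
#' contents"}), the treatment used for bladder contents when a model routes
#' activity to urine.
#'
#' @inheritParams uptake_sweep
#' @param F maximum thyroid uptake fraction.
#' @return a \code{cumulated_activity_set}.
#' @export
pipeline_activities <- function(nuclide, F,
                                constants = iodide_default_constants(),
                                schedule = voiding_schedule()) {
  m <- build_iodide_pregnancy_model(F, nuclide, constants)
  ca <- cumulated_activities(m)
  bl <- bladder_cumulated_activity(urine_inflow_function(m), m$lambda_phys,
                                   schedule)
  ent <- ca$entries
  ent <- ent[setdiff(names(ent), "urine")]
  ent[["urinary bladder contents"]] <- bl
  cumulated_activity_set(ent, nuclide = nuclide, uptake = F,
                         provenance = "computed",
                         compartment_hours = ca$compartment_hours)
}

#' Compare organ doses across cumulated-activity provenances
#'
#' Computes one dose column per activity set on the same S-values and the
#' pairwise percent differences \code{100 * (a - b) / b} against a named
#' base column (the base is stated explicitly in the output header because
#' percent comparisons are base-dependent). When a set lacks the fetal
#' thyroid as a separate source but carries a whole-fetus entry, the fetus is
#' treated as a single uniform source region.
#'
#' @param sets named list of \code{cumulated_activity_set}s.
#' @param svalues an \code{svalue_set} that includes a \code{"fetus"} source
#'   for the uniform-fetus scenario.
#' @param base name of the comparison base column.
#' @return data.frame: targets x dose columns plus \code{pct_diff_<set>_vs_<base>}.
#' @export
compare_activity_sets <- function(sets, svalues, base = names(sets)[1]) {
  stopifnot(base %in% names(sets))
  cols <- lapply(sets, function(a) organ_doses(svalues, a))
  targets <- cols[[1]]$target
  out <- data.frame(target = targets, stringsAsFactors = FALSE)
  for (nm in names(cols))
    out[[nm]] <- cols[[nm]]$dose[match(targets, cols[[nm]]$target)]
  for (nm in setdiff(names(cols), base))
    out[[paste0("pct_diff_", nm, "_vs_", base)]] <-
      ifelse(out[[base]] > 0, 100 * (out[[nm]] - out[[base]]) / out[[base]],
             NA_real_)
  attr(out, "base") <- base
  out
}

#' Whole-fetus dose summary
#'
#' Mass-weighted mean of the fetal-region doses, identical to total fetal
#' energy over total fetal mass.
#'
#' @param doses named numeric vector of per-fetal-region doses.
#' @param masses named numeric vector of the matching region masses (g).
#' @return scalar fetus dose.
#' @export
fetal_summary <- function(doses, masses) {
  miss <- setdiff(names(doses), names(masses))
  if (length(miss)) stop("missing fetal masses for: ",
                         paste(miss, collapse = ", "))
  m <- masses[names(doses)]
  sum(doses * m) / sum(m)
}

#' Render a sagittal dose-map slice to PNG
#'
#' Logarithmic color scale over the positive doses; masked (air) voxels
#' render black. Requires the \pkg{png} package.
#'
#' @param dose_map 3-D dose array from \code{\link{mesh_dose_map}}.
#' @param path output PNG path.
#' @param axis slicing axis (1 = x: sagittal for this phantom).
#' @param index slice index; default the middle.
#' @param decades dynamic range in decades below the maximum.
#' @return invisibly \code{path}.
#' @export
render_dose_map <- function(dose_map, path, axis = 1L, index = NULL,
                            decades = 4) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("render_dose_map needs the 'png' package")
  d <- dim(dose_map)
  if (is.null(index)) index <- ceiling(d[axis] / 2)
  sl <- switch(axis, dose_map[index, , ], dose_map[, index, ],
               dose_map[, , index])
  lo <- log10(max(sl, na.rm = TRUE)) - decades
  v <- (log10(pmax(sl, 10^lo)) - lo) / decades
  v[is.na(sl)] <- NA
  pal <- grDevices::hcl.colors(256, "Inferno")
  rgbm <- grDevices::col2rgb(pal[pmin(pmax(ceiling(v * 255), 1), 256)]) / 255
  img <- array(0, dim = c(ncol(sl), nrow(sl), 3))
  for (ch in 1:3) {
    m <- matrix(rgbm[ch, ], nrow = nrow(sl))
    m[is.na(v)] <- 0
    img[, , ch] <- t(m)[rev(seq_len(ncol(sl))), , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}
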