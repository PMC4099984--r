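# Fixture tables and CSV round-trip for cumulated activities.

.unit_to_hours <- function(value, unit) {
  f <- c(s = 1 / 3600, min = 1 / 60, h = 1, d = 24)
  if (any(!unit %in% names(f))) stop("unknown time unit: ",
                                     paste(setdiff(unit, names(f)), collapse = ","))
  value * f[unit]
}

#' Load packaged cumulated-activity tables
#'
#' Returns the transcribed comparison-table values for the requested
#' (provenance, nuclide, uptake) triple, converted to hours. \code{"russell"}
#' and \code{"icrp53"} are reference data sets (inputs, not outputs of this
#' package); \code{"this_study"} is the transcription of the published
#' compartmental solution, useful for consistency checks against
#' \code{\link{cumulated_activities}} trends.
#'
#' @param source \code{"russell"}, \code{"icrp53"} or \code{"this_study"}.
#' @param nuclide \code{"I-131"}, \code{"I-123"} or \code{"Tc-99m"}.
#' @param uptake maximum thyroid uptake fraction (ignored for Tc-99m).
#' @return a \code{\link{cumulated_activity_set}}.
#' @export
load_fixture_activities <- function(source = c("russell", "icrp53", "this_study"),
                                    nuclide, uptake = 0.25) {
  source <- match.arg(source)
  df <- read.csv(.extdata("cumulated_activities.csv"), comment.char = "#",
                 stringsAsFactors = FALSE)
  sel <- df$nuclide == nuclide & df$provenance == source
  if (nuclide != "Tc-99m") {
    sel <- sel & !is.na(df$uptake) & abs(df$uptake - uptake) < 1e-9
  } else uptake <- NA_real_
  sub <- df[sel, ]
  if (!nrow(sub))
    stop("no fixture activities for (", source, ", ", nuclide, ", ",
         uptake, ")")
  hrs <- .unit_to_hours(sub$value, sub$unit)
  cumulated_activity_set(setNames(hrs, sub$region), nuclide = nuclide,
                         uptake = uptake, provenance = source)
}

#' Write / read a cumulated-activity set as CSV
#'
#' Columns: \code{region}, \code{A_hours}, \code{nuclide}, \code{uptake},
#' \code{provenance}. \code{read_activities(write_activities(x))} is
#' an identity.
#'
#' @param x a \code{cumulated_activity_set}.
#' @param path file path.
#' @export
write_activities <- function(x, path) {
  df <- data.frame(region = names(x$entries), A_hours = as.numeric(x$entries),
                   nuclide = x$nuclide, uptake = x$uptake,
                   provenance = x$provenance, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activities
#' @export
read_activities <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "A_hours", "nuclide", "uptake", "provenance")
  if (!all(need %in% names(df)))
    stop("malformed activities CSV (need columns ",
         paste(need, collapse = ", "), "): ", path)
  cumulated_activity_set(setNames(df$A_hours, df$region),
                         nuclide = df$nuclide[1], uptake = df$uptake[1],
                         provenance = df$provenance[1])
}

#' Packaged organ-mass comparison table
#'
#' The reference-vs-voxelized mass table of the pregnant model (maternal
#' block at ICRP 110 reference masses, fetal block at ICRP 89), including the
#' printed percent differences.
#' @return data.frame with columns \code{block}, \code{organ},
#'   \code{reference_g}, \code{new_g}, \code{printed_diff_pct}.
#' @export
load_reference_masses <- function() {
  read.csv(.extdata("reference_masses.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}

#' Packaged organ-dose table for I-131
#'
#' Transcription of the published organ-dose table (mGy/MBq) for I-131
#' sodium iodide: this-study columns over the seven uptake levels plus the
#' reference-activity columns and previously reported stylized-model values.
#' @return data.frame with columns \code{nuclide}, \code{provenance},
#'   \code{uptake}, \code{target}, \code{dose_mGy_per_MBq}.
#' @export
load_dose_table <- function() {
  read.csv(.extdata("organ_doses_I-131.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}

#' Active-marrow mass fractions by skeletal site
#' @return data.frame with columns \code{site}, \code{fraction} (sums to 1).
#' @export
load_marrow_fractions <- function() {
  read.csv(.extdata("marrow_fractions.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}

#' Read an iodide rate-constant bundle from YAML
#' @param path YAML file; default: the packaged bundle.
#' @return named list usable as the \code{constants} argument of
#'   \code{\link{build_iodide_pregnancy_model}}.
#' @export
read_constants_bundle <- function(path = .extdata("iodide_constants.yaml")) {
  yaml::read_yaml(path)
}
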