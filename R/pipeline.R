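# pipeline_io: orchestration, configuration, container round-trips.

#' Pipeline run configuration
#'
#' @param profile scene profile (\code{"reference_9mo"} or
#'   \code{"minimal_test"}).
#' @param spacing voxel spacing, mm.
#' @param nuclide nuclide name.
#' @param uptake maximum thyroid uptake fraction(s) for iodide nuclides.
#' @param n_histories Monte Carlo histories per emission run.
#' @param seed master seed.
#' @param electron_mode \code{"local"} or \code{"csda"}.
#' @param activities \code{"computed"}, \code{"russell"} or \code{"icrp53"}.
#' @param outdir output directory.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(profile = "reference_9mo", spacing = 4,
                       nuclide = "I-131", uptake = 0.25,
                       n_histories = 2000L, seed = 1L,
                       electron_mode = "local", activities = "computed",
                       outdir = tempfile("fetodose_run_")) {
  cfg <- list(profile = profile, spacing = spacing, nuclide = nuclide,
              uptake = uptake, n_histories = as.integer(n_histories),
              seed = seed, electron_mode = electron_mode,
              activities = activities, outdir = outdir)
  class(cfg) <- "run_config"
  cfg
}

#' Fail-fast validation of a run configuration
#'
#' Checks every referenced fixture and keyword before any stage runs.
#' @param config a \code{run_config}.
#' @return invisibly \code{TRUE}.
#' @export
validate_run_config <- function(config) {
  if (!config$profile %in% c("reference_9mo", "minimal_test"))
    stop("unknown profile: ", config$profile)
  .extdata(.decay_file(config$nuclide))              # errors if absent
  if (config$activities != "computed") {
    load_fixture_activities(config$activities, config$nuclide,
                            config$uptake[1])
  } else if (!config$nuclide %in% c("I-131", "I-123")) {
    stop("computed activities require an iodide nuclide; use a fixture ",
         "provenance for ", config$nuclide)
  }
  if (!config$electron_mode %in% c("local", "csda"))
    stop("unknown electron mode: ", config$electron_mode)
  stopifnot(config$n_histories >= 1, all(config$spacing > 0))
  invisible(TRUE)
}

.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full dosimetry pipeline
#'
#' Executes the stages in order -- scene construction, voxelization plus mass
#' adjustment, cumulated activities (computed or fixture), decay-scheme
#' preparation (yield cutoff, electron-line collapse), Monte Carlo transport
#' per emission, S-value assembly and organ doses -- writing CSV outputs and
#' a JSON manifest to \code{config$outdir}. The voxelization stage is cached
#' by a content hash of the fields it depends on, so re-running with an
#' identical configuration reuses the lattice and reproduces identical
#' outputs.
#'
#' @param config a \code{run_config}.
#' @return list with the lattice, activities, S-values, dose table(s),
#'   mass report and the manifest (invisibly written as files too).
#' @export
run_pipeline <- function(config = run_config()) {
  validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[fetodose] ", sprintf(...))

  scene <- build_reference_scene(config$profile)

  geo_key <- .config_hash(config[c("profile", "spacing")])
  cache <- file.path(config$outdir, paste0("lattice_", geo_key, ".txt.gz"))
  if (file.exists(cache)) {
    log_stage("voxelize: cached lattice %s", basename(cache))
    lattice <- read_lattice(cache)
  } else {
    log_stage("voxelize: spacing %s mm", paste(config$spacing, collapse = "x"))
    lattice <- voxelize_scene(scene, config$spacing)
    lattice <- adjust_scene_masses(lattice, scene)
    write_lattice(lattice, cache)
  }
  mrep <- mass_report(lattice)
  write.csv(mrep, file.path(config$outdir, "mass_report.csv"),
            row.names = FALSE)

  log_stage("activities: %s", config$activities)
  acts <- lapply(config$uptake, function(F) {
    if (config$activities == "computed")
      pipeline_activities(config$nuclide, F)
    else load_fixture_activities(config$activities, config$nuclide, F)
  })
  names(acts) <- sprintf("%g", config$uptake)
  for (nm in names(acts))
    write_activities(acts[[nm]],
                     file.path(config$outdir,
                               sprintf("activities_u%s.csv", nm)))

  log_stage("decay scheme: %s", config$nuclide)
  scheme <- collapse_electron_lines(
    apply_yield_cutoff(load_scheme(config$nuclide)))

  log_stage("transport: %d histories x %d emissions", config$n_histories,
            nrow(scheme_runs(scheme)))
  xs <- xs_table()
  srcs <- if (config$profile == "reference_9mo") {
    sr <- source_region_labels(scene)
    present <- lattice$label_table$label
    sr <- lapply(sr, function(l) l[l %in% present])
    sr[vapply(sr, length, integer(1)) > 0]
  } else {
    lt <- lattice$label_table
    labs <- lt$label[lt$source]
    setNames(as.list(labs), lt$region[lt$source])
  }
  cfg <- transport_config(n_histories = config$n_histories,
                          seed = config$seed,
                          electron_mode = config$electron_mode)
  sv <- compute_svalues(lattice, xs, scheme, srcs, cfg)
  write.csv(as.data.frame(sv), file.path(config$outdir, "svalues.csv"),
            row.names = FALSE)

  log_stage("doses")
  doses <- lapply(acts, function(a) {
    ent <- a$entries
    keep <- canonical_region(names(ent)) %in%
      c(canonical_region(names(srcs)), "urine", "feces")
    if (!any(keep))
      warning("no activity region maps onto a source region of profile '",
              config$profile, "'; doses will be zero", call. = FALSE)
    a$entries <- ent[keep]
    organ_doses(sv, a)
  })
  for (nm in names(doses))
    write.csv(as.data.frame(doses[[nm]]),
              file.path(config$outdir, sprintf("doses_u%s.csv", nm)),
              row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fetodose")),
    config = unclass(config[setdiff(names(config), "outdir")]),
    lattice_dims = lattice$dims,
    lattice_hash = unname(tools::md5sum(cache)),
    scheme_checksum = scheme_checksum(config$nuclide),
    n_emission_runs = nrow(scheme_runs(scheme)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(config$outdir, "manifest.json"))
  invisible(list(lattice = lattice, mass_report = mrep, activities = acts,
                 svalues = sv, doses = doses, manifest = manifest))
}

# --- lattice container ------------------------------------------------------

#' Write / read a label lattice container
#'
#' Plain-text container (gzip-compressed by default when the path ends in
#' \code{.gz}): a header with dims, spacing (mm), origin (mm) and the label
#' table, followed by the label array as run-length encoded \code{value
#' count} pairs in x-fastest order. Round-trips are bit-exact. A portable
#' binary variant (\code{format = "binary"}, RDS serialization) is also
#' supported.
#'
#' @param lattice a \code{label_lattice}.
#' @param path output path (\code{.gz} suffix compresses the text format).
#' @param format \code{"text"} or \code{"binary"}.
#' @return \code{write_lattice}: invisibly \code{path};
#'   \code{read_lattice}: the lattice.
#' @export
write_lattice <- function(lattice, path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    saveRDS(lattice, path)
    return(invisible(path))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  fmtnum <- function(x) sprintf("%.17g", x)
  writeLines("fetodose-lattice 1", con)
  writeLines(paste("dims", paste(lattice$dims, collapse = " ")), con)
  writeLines(paste("spacing", paste(fmtnum(lattice$spacing), collapse = " ")), con)
  writeLines(paste("origin", paste(fmtnum(lattice$origin), collapse = " ")), con)
  lt <- lattice$label_table
  writeLines(paste("labels", nrow(lt)), con)
  for (r in seq_len(nrow(lt)))
    writeLines(paste(lt$label[r], lt$material[r], fmtnum(lt$density[r]),
                     fmtnum(lt$target_mass[r]), as.integer(lt$source[r]),
                     as.integer(lt$fetal[r]), lt$region[r], lt$name[r],
                     sep = "\t"), con)
  rl <- rle(as.vector(lattice$labels))
  writeLines(paste("rle", length(rl$values)), con)
  writeLines(paste(rl$values, rl$lengths), con)
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "binary") return(readRDS(path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!identical(magic, "fetodose-lattice 1"))
    stop("not a fetodose lattice container: ", path)
  rd <- function(key) {
    parts <- strsplit(readLines(con, 1), " ")[[1]]
    if (parts[1] != key) stop("malformed lattice header (expected ", key, ")")
    as.numeric(parts[-1])
  }
  dims <- as.integer(rd("dims"))
  spacing <- rd("spacing")
  origin <- rd("origin")
  nlt <- as.integer(rd("labels"))
  ltl <- readLines(con, nlt)
  if (length(ltl) != nlt) stop("truncated lattice container: ", path)
  f <- strsplit(ltl, "\t", fixed = TRUE)
  lt <- data.frame(
    label = as.integer(vapply(f, `[`, "", 1)),
    name = vapply(f, `[`, "", 8),
    region = vapply(f, `[`, "", 7),
    material = vapply(f, `[`, "", 2),
    density = as.numeric(vapply(f, `[`, "", 3)),
    target_mass = suppressWarnings(as.numeric(vapply(f, `[`, "", 4))),
    source = as.logical(as.integer(vapply(f, `[`, "", 5))),
    fetal = as.logical(as.integer(vapply(f, `[`, "", 6))),
    stringsAsFactors = FALSE)
  nr <- as.integer(rd("rle"))
  rll <- readLines(con)
  if (length(rll) != nr) stop("truncated lattice container: ", path)
  m <- matrix(as.integer(unlist(strsplit(rll, " ", fixed = TRUE))),
              ncol = 2, byrow = TRUE)
  vec <- rep(m[, 1], m[, 2])
  if (length(vec) != prod(dims)) stop("lattice size mismatch in ", path)
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 labels = array(vec, dim = dims), label_table = lt),
            class = "label_lattice")
}
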