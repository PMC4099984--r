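# phantom_synth: synthetic pregnant-anatomy scenes.

#' Build a synthetic pregnant-anatomy scene
#'
#' Constructs a \code{phantom_scene}: a body envelope plus a list of organ
#' specifications (geometric primitive, target mass, material, optional
#' nesting parent and source-region flag). The \code{"reference_9mo"} profile
#' carries the maternal source-organ roster (thyroid 17 g, stomach wall 140 g
#' plus contents, small-intestine wall 600 g plus contents, liver 1400 g,
#' kidneys, urinary bladder contents 200 g, salivary glands, residual trunk
#' tissue) and a 20-organ fetus at ICRP 89 reference masses, including the
#' 1.3 g fetal thyroid; fetal target masses sum to 3471.82 g (within 1\% of
#' the 3500 g reference fetus). \code{"minimal_test"} returns a 4-organ scene
#' for fast tests.
#'
#' @param profile \code{"reference_9mo"} or \code{"minimal_test"}.
#' @return an object of class \code{phantom_scene} with fields
#'   \code{organs}, \code{envelope}, \code{materials}, \code{fetus_labels},
#'   \code{grid_hint} (mm) and \code{profile}.
#' @examples
#' sc <- build_reference_scene("minimal_test")
#' print(sc)
#' @export
build_reference_scene <- function(profile = c("reference_9mo", "minimal_test")) {
  if (!is.character(profile) || !profile[1] %in% c("reference_9mo", "minimal_test"))
    stop("unknown scene profile: ", paste(profile[1], collapse = ""))
  profile <- profile[1]
  if (profile == "reference_9mo") {
    organs <- .reference_layout()
    envelope <- list(
      label = 90L, name = "residual tissue, trunk", region = "residual tissue",
      shape = .ell(c(0, 0, 0), c(200, 180, 380)), material = "soft_tissue",
      source_flag = TRUE)
    fetus_labels <- sort(vapply(Filter(function(o) o$fetal, organs),
                                `[[`, integer(1), "label"))
    grid_hint <- c(2, 2, 2)
  } else {
    organs <- .minimal_layout()
    envelope <- list(
      label = 9L, name = "body", region = "body",
      shape = .sph(c(0, 0, 0), 80), material = "soft_tissue",
      source_flag = TRUE)
    fetus_labels <- integer(0)
    grid_hint <- c(4, 4, 4)
  }
  sc <- structure(list(profile = profile, organs = organs, envelope = envelope,
                       materials = material_table(profile),
                       fetus_labels = fetus_labels, grid_hint = grid_hint),
                  class = "phantom_scene")
  .check_scene_refs(sc)
  sc
}

# referential integrity: unique labels, positive masses, materials resolve,
# parents exist.
.check_scene_refs <- function(sc) {
  labs <- vapply(sc$organs, `[[`, integer(1), "label")
  if (anyDuplicated(c(labs, sc$envelope$label)))
    stop("duplicate organ labels in scene")
  if (any(vapply(sc$organs, `[[`, numeric(1), "target_mass") <= 0))
    stop("non-positive target mass")
  mats <- c(vapply(sc$organs, `[[`, character(1), "material"),
            sc$envelope$material,
            unlist(lapply(sc$organs,
                          function(o) o$wall$wall_material %||% character(0))))
  missing <- setdiff(unique(mats), names(sc$materials))
  if (length(missing)) stop("unresolved materials: ", paste(missing, collapse = ", "))
  par <- vapply(sc$organs, `[[`, integer(1), "parent")
  bad <- setdiff(par[!is.na(par)], labs)
  if (length(bad)) stop("unknown parent labels: ", paste(bad, collapse = ", "))
  invisible(sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scene_organ <- function(scene, label) {
  for (o in scene$organs) if (o$label == label) return(o)
  if (label == scene$envelope$label) return(scene$envelope)
  stop("no organ with label ", label)
}

# nesting depth (envelope/top-level = 0)
.organ_depths <- function(scene) {
  labs <- vapply(scene$organs, `[[`, integer(1), "label")
  par <- vapply(scene$organs, `[[`, integer(1), "parent")
  depth <- integer(length(labs))
  for (i in seq_along(labs)) {
    d <- 0L; p <- par[i]
    while (!is.na(p)) { d <- d + 1L; p <- par[match(p, labs)] }
    depth[i] <- d
  }
  depth
}

#' Validate a phantom scene geometrically
#'
#' Checks, by uniform interior point sampling, that every organ primitive lies
#' inside the body envelope and that every nested organ lies inside its
#' parent's primitive.
#'
#' @param scene a \code{phantom_scene}.
#' @param n points sampled per organ.
#' @param seed RNG seed for the sampling.
#' @return invisibly \code{TRUE}; stops with the offending organ otherwise.
#' @export
validate_scene <- function(scene, n = 2000L, seed = 1L) {
  set.seed(seed)
  labs <- vapply(scene$organs, `[[`, integer(1), "label")
  for (o in scene$organs) {
    pts <- sample_primitive(o$shape, n)
    if (!all(inside_primitive(scene$envelope$shape, pts[, 1], pts[, 2], pts[, 3])))
      stop("organ outside envelope: ", o$name)
    if (!is.na(o$parent)) {
      pp <- scene$organs[[match(o$parent, labs)]]$shape
      if (!all(inside_primitive(pp, pts[, 1], pts[, 2], pts[, 3])))
        stop("organ outside its parent: ", o$name)
    }
  }
  invisible(TRUE)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom_scene '%s': %d organs (%d fetal, %d source regions)\n",
              x$profile, length(x$organs), length(x$fetus_labels),
              sum(vapply(x$organs, `[[`, logical(1), "source_flag"))))
  tm <- vapply(x$organs, `[[`, numeric(1), "target_mass")
  cat(sprintf("  total organ target mass %.1f g; grid hint %s mm\n",
              sum(tm), paste(x$grid_hint, collapse = "x")))
  invisible(x)
}

#' @export
summary.phantom_scene <- function(object, ...) {
  df <- data.frame(
    label = vapply(object$organs, `[[`, integer(1), "label"),
    name = vapply(object$organs, `[[`, character(1), "name"),
    region = vapply(object$organs, `[[`, character(1), "region"),
    shape = vapply(object$organs, function(o) o$shape$type, character(1)),
    target_mass_g = vapply(object$organs, `[[`, numeric(1), "target_mass"),
    material = vapply(object$organs, `[[`, character(1), "material"),
    parent = vapply(object$organs, `[[`, integer(1), "parent"),
    source = vapply(object$organs, `[[`, logical(1), "source_flag"),
    fetal = vapply(object$organs, `[[`, logical(1), "fetal"),
    stringsAsFactors = FALSE)
  df[order(df$label), ]
}

#' Serialize a scene to JSON (and read it back)
#'
#' The serialization is canonical (fixed field order, full precision), so
#' identical profiles produce byte-identical files.
#'
#' @param scene a \code{phantom_scene}.
#' @param path output file.
#' @return \code{write_scene}: invisibly \code{path}; \code{read_scene}: the
#'   scene.
#' @export
write_scene <- function(scene, path) {
  js <- jsonlite::serializeJSON(unclass(scene), digits = NA, pretty = TRUE)
  writeLines(js, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  sc <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  class(sc) <- "phantom_scene"
  class(sc$materials) <- "material_table"
  .check_scene_refs(sc)
  sc
}
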