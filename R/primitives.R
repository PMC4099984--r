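# Geometric primitives for synthetic organs.
#
# All lengths are millimetres. A primitive is a plain list with a `type`
# field and type-specific parameters; supported types are
#   ellipsoid       : center, semi = c(a, b, c)
#   sphere          : center, radius
#   box             : center, half = c(hx, hy, hz)   (axis-aligned)
#   capsule         : center, radius, length, axis ("x"|"y"|"z")
#                     (`length` is the cylindrical part; total extent along the
#                      axis is length + 2*radius)
#   spherical_shell : center, r_inner, r_outer
# Points exactly on a boundary classify as inside (closed surfaces), so the
# classification is deterministic; the effect is measure zero.

primitive <- function(type, center, ...) {
  p <- c(list(type = type, center = as.numeric(center)), list(...))
  validate_primitive(p)
  p
}

validate_primitive <- function(p) {
  stopifnot(is.list(p), !is.null(p$type), length(p$center) == 3L,
            all(is.finite(p$center)))
  switch(p$type,
    ellipsoid = stopifnot(length(p$semi) == 3L, all(p$semi > 0)),
    sphere = stopifnot(p$radius > 0),
    box = stopifnot(length(p$half) == 3L, all(p$half > 0)),
    capsule = stopifnot(p$radius > 0, p$length >= 0,
                        p$axis %in% c("x", "y", "z")),
    spherical_shell = stopifnot(p$r_inner >= 0, p$r_outer > p$r_inner),
    ellipsoid_shell = stopifnot(length(p$semi_outer) == 3L,
                                length(p$semi_inner) == 3L,
                                all(p$semi_outer > p$semi_inner),
                                all(p$semi_inner > 0)),
    stop("unknown primitive type: ", p$type)
  )
  invisible(p)
}

#' Test whether points lie inside a geometric primitive
#'
#' Vectorized point-in-solid classification; boundary points count as inside.
#'
#' @param prim a primitive list (see package sources for the schema).
#' @param x,y,z numeric vectors of coordinates in mm.
#' @return logical vector.
#' @export
inside_primitive <- function(prim, x, y, z) {
  cx <- x - prim$center[1]; cy <- y - prim$center[2]; cz <- z - prim$center[3]
  switch(prim$type,
    ellipsoid = (cx / prim$semi[1])^2 + (cy / prim$semi[2])^2 +
                (cz / prim$semi[3])^2 <= 1,
    sphere = cx * cx + cy * cy + cz * cz <= prim$radius^2,
    box = abs(cx) <= prim$half[1] & abs(cy) <= prim$half[2] &
          abs(cz) <= prim$half[3],
    capsule = {
      h <- prim$length / 2
      ax <- switch(prim$axis, x = cx, y = cy, z = cz)
      d1 <- switch(prim$axis, x = cy, y = cx, z = cx)
      d2 <- switch(prim$axis, x = cz, y = cz, z = cy)
      # distance to the axis segment [-h, h]
      aclamp <- pmin(pmax(ax, -h), h)
      d1 * d1 + d2 * d2 + (ax - aclamp)^2 <= prim$radius^2
    },
    spherical_shell = {
      r2 <- cx * cx + cy * cy + cz * cz
      r2 >= prim$r_inner^2 & r2 <= prim$r_outer^2
    },
    ellipsoid_shell = {
      fo <- (cx / prim$semi_outer[1])^2 + (cy / prim$semi_outer[2])^2 +
            (cz / prim$semi_outer[3])^2
      fi <- (cx / prim$semi_inner[1])^2 + (cy / prim$semi_inner[2])^2 +
            (cz / prim$semi_inner[3])^2
      fo <= 1 & fi > 1
    },
    stop("unknown primitive type: ", prim$type)
  )
}

#' Analytic volume of a primitive in mm^3
#' @param prim a primitive list.
#' @return volume in mm^3.
#' @export
primitive_volume <- function(prim) {
  switch(prim$type,
    ellipsoid = 4 / 3 * pi * prod(prim$semi),
    sphere = 4 / 3 * pi * prim$radius^3,
    box = 8 * prod(prim$half),
    capsule = pi * prim$radius^2 * prim$length + 4 / 3 * pi * prim$radius^3,
    spherical_shell = 4 / 3 * pi * (prim$r_outer^3 - prim$r_inner^3),
    ellipsoid_shell = 4 / 3 * pi * (prod(prim$semi_outer) - prod(prim$semi_inner)),
    stop("unknown primitive type: ", prim$type)
  )
}

# Axis-aligned bounding box, rows = (min, max), cols = x,y,z.
primitive_bbox <- function(prim) {
  ext <- switch(prim$type,
    ellipsoid = prim$semi,
    sphere = rep(prim$radius, 3),
    box = prim$half,
    capsule = {
      e <- rep(prim$radius, 3)
      i <- match(prim$axis, c("x", "y", "z"))
      e[i] <- e[i] + prim$length / 2
      e
    },
    spherical_shell = rep(prim$r_outer, 3),
    ellipsoid_shell = prim$semi_outer
  )
  rbind(min = prim$center - ext, max = prim$center + ext)
}

# Uniform rejection sampling of interior points; used by scene validation.
sample_primitive <- function(prim, n, max_tries = 50L) {
  bb <- primitive_bbox(prim)
  out <- matrix(NA_real_, 0, 3)
  for (i in seq_len(max_tries)) {
    m <- max(2L * n, 100L)
    pts <- cbind(runif(m, bb[1, 1], bb[2, 1]),
                 runif(m, bb[1, 2], bb[2, 2]),
                 runif(m, bb[1, 3], bb[2, 3]))
    keep <- inside_primitive(prim, pts[, 1], pts[, 2], pts[, 3])
    out <- rbind(out, pts[keep, , drop = FALSE])
    if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
  }
  stop("sample_primitive: rejection sampling failed (degenerate primitive?)")
}
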