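#' Bone surface mesh
#'
#' A closed triangulated surface of one bone side: an `n x 3` vertex matrix
#' (mm), an `m x 3` integer face matrix (1-based vertex indices, outward
#' counter-clockwise winding), a side label and optional specimen metadata.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle.
#' @param side `"left"` or `"right"`.
#' @param specimen,species,stage optional metadata labels.
#' @param aligned logical, set by [align_to_standard_position()].
#' @return object of class `bone_surface`.
#' @export
bone_surface <- function(vertices, faces, side = c("left", "right"),
                         specimen = NA_character_, species = NA_character_,
                         stage = NA_integer_, aligned = FALSE) {
  side <- match.arg(side)
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop_osteofa("vertices must have 3 columns")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop_osteofa("face indices out of range")
  }
  structure(
    list(vertices = vertices, faces = faces, side = side,
         specimen = specimen, species = species, stage = stage,
         aligned = isTRUE(aligned)),
    class = "bone_surface"
  )
}

#' @export
print.bone_surface <- function(x, ...) {
  cat("<bone_surface>", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces, side =", x$side,
      if (x$aligned) "(aligned)" else "", "\n")
  invisible(x)
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume (sum of signed tetrahedra); positive for
#' outward-wound watertight surfaces.
#'
#' @param mesh a [bone_surface()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  cx <- p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]
  cy <- p2[, 3L] * p3[, 1L] - p2[, 1L] * p3[, 3L]
  cz <- p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L]
  sum(p1[, 1L] * cx + p1[, 2L] * cy + p1[, 3L] * cz) / 6
}

# Edge keys "i_j" with i < j, 3 per face.
mesh_edge_keys <- function(faces) {
  a <- c(faces[, 1L], faces[, 2L], faces[, 3L])
  b <- c(faces[, 2L], faces[, 3L], faces[, 1L])
  paste(pmin(a, b), pmax(a, b), sep = "_")
}

#' Check that every edge is shared by exactly two faces
#' @param mesh a [bone_surface()].
#' @return logical; attributes carry the offending edge count.
#' @export
mesh_is_manifold <- function(mesh) {
  tab <- table(mesh_edge_keys(mesh$faces))
  bad <- sum(tab != 2L)
  structure(bad == 0L, bad_edges = bad)
}

#' Build a synthetic watertight bone mesh
#'
#' Extrudes a star-shaped cross-section profile along the long (z) axis to
#' total length `hl`, scales the section by `radius_profile(t)` at each
#' axial fraction `t` in `[0, 1]`, caps both ends with triangle fans, and
#' optionally applies a rigid rotation. Right-side meshes are mirrored
#' copies (first coordinate negated) with faces re-wound so normals stay
#' outward.
#'
#' @param hl total bone length (mm), > 0.
#' @param radius_profile function axial fraction -> positive scale factor
#'   applied to the unit section (default constant 1).
#' @param section a `section_contour` giving the unit cross-section shape
#'   (default unit circle with `n_vertices` vertices).
#' @param orientation 3x3 rotation matrix applied to the finished mesh.
#' @param side `"left"` or `"right"`.
#' @param n_axial number of axial segments (odd by default so no vertex ring
#'   falls exactly on the midshaft plane).
#' @param n_vertices vertices in the default circular section.
#' @param specimen,species,stage metadata labels.
#' @return a [bone_surface()].
#' @export
#' @examples
#' m <- make_bone_mesh(10, section = make_contour("circle", list(r = 1), 64))
#' humeral_length(align_to_standard_position(m))
make_bone_mesh <- function(hl,
                           radius_profile = function(t) 1,
                           section = NULL,
                           orientation = diag(3),
                           side = c("left", "right"),
                           n_axial = 33L,
                           n_vertices = 64L,
                           specimen = NA_character_,
                           species = NA_character_,
                           stage = NA_integer_) {
  side <- match.arg(side)
  if (hl <= 0) stop_osteofa("hl must be positive")
  if (is.null(section)) {
    section <- make_contour("circle", list(r = 1), n_vertices)
  }
  prof <- section$vertices
  k <- nrow(prof)
  tfrac <- seq(0, 1, length.out = n_axial + 1L)
  scales <- vapply(tfrac, radius_profile, numeric(1))
  if (any(scales <= 0)) stop_osteofa("radius_profile must be positive on [0, 1]")

  zs <- tfrac * hl - hl / 2
  verts <- do.call(rbind, lapply(seq_along(tfrac), function(j) {
    cbind(prof * scales[j], zs[j])
  }))
  n_rings <- length(tfrac)
  # side wall quads between consecutive rings, split into two triangles;
  # contour is CCW viewed from +z, so this winding points normals outward
  faces <- do.call(rbind, lapply(seq_len(n_rings - 1L), function(j) {
    lo <- (j - 1L) * k
    hi <- j * k
    i1 <- lo + seq_len(k)
    i2 <- lo + c(seq_len(k)[-1L], 1L)
    j1 <- hi + seq_len(k)
    j2 <- hi + c(seq_len(k)[-1L], 1L)
    rbind(cbind(i1, i2, j2), cbind(i1, j2, j1))
  }))
  # end caps: fans to pole vertices at the ring centroids
  bottom_pole <- nrow(verts) + 1L
  top_pole <- nrow(verts) + 2L
  verts <- rbind(verts,
                 c(colMeans(prof * scales[1L]), zs[1L]),
                 c(colMeans(prof * scales[n_rings]), zs[n_rings]))
  b1 <- seq_len(k)
  b2 <- c(seq_len(k)[-1L], 1L)
  t1 <- (n_rings - 1L) * k + seq_len(k)
  t2 <- (n_rings - 1L) * k + c(seq_len(k)[-1L], 1L)
  faces <- rbind(faces,
                 cbind(b2, b1, bottom_pole),   # bottom cap faces -z
                 cbind(t1, t2, top_pole))      # top cap faces +z
  colnames(faces) <- NULL

  if (side == "right") {
    verts[, 1L] <- -verts[, 1L]
    faces <- faces[, c(1L, 3L, 2L)]
  }
  orientation <- as.matrix(orientation)
  if (!isTRUE(all.equal(crossprod(orientation), diag(3), tolerance = 1e-8))) {
    stop_osteofa("orientation must be an orthonormal rotation matrix")
  }
  verts <- verts %*% t(orientation)
  bone_surface(verts, faces, side = side, specimen = specimen,
               species = species, stage = stage)
}

#' Rigidly align a bone mesh to the standard measuring position
#'
#' Centres the vertex cloud on its centroid and rotates it so that the
#' dominant principal axis of the vertex scatter (the long axis) lies along
#' the third coordinate and the second principal axis (taken as the
#' antero-posterior axis) along the first coordinate. Axis signs are fixed
#' deterministically: each of the long and AP axes is flipped so the vertex
#' distribution along it has positive skewness (falling back to a
#' lexicographic sign rule when skewness is ~0), and the remaining axis is
#' their cross product, so the transform is always a proper rotation.
#'
#' @param mesh a [bone_surface()].
#' @param min_axis_ratio minimum ratio of first to second eigenvalue below
#'   which there is no dominant long axis (default 1.05).
#' @return the aligned [bone_surface()] (`$aligned` set).
#' @export
align_to_standard_position <- function(mesh, min_axis_ratio = 1.05) {
  stopifnot(inherits(mesh, "bone_surface"))
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  cv <- crossprod(vc) / (nrow(vc) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  if (any(eg$values <= 0) || eg$values[2L] <= 0) {
    stop_osteofa("alignment failure: degenerate vertex scatter")
  }
  if (eg$values[1L] / eg$values[2L] < min_axis_ratio) {
    stop_osteofa("alignment failure: no dominant long axis (eigenvalue ",
                 "ratio ", format(eg$values[1L] / eg$values[2L], digits = 4),
                 " < ", min_axis_ratio, ")")
  }
  fix_sign <- function(u) {
    p <- vc %*% u
    s <- stats::sd(p)
    skew <- if (s > 0) mean((p / s)^3) else 0
    if (abs(skew) > 1e-8) {
      if (skew < 0) -u else u
    } else {
      # lexicographic fallback: largest-magnitude component positive
      i <- which.max(abs(u))
      if (u[i] < 0) -u else u
    }
  }
  b_long <- fix_sign(eg$vectors[, 1L])  # -> coordinate 3
  b_ap <- fix_sign(eg$vectors[, 2L])    # -> coordinate 1 (antero-posterior)
  b_mid <- c(b_long[2L] * b_ap[3L] - b_long[3L] * b_ap[2L],
             b_long[3L] * b_ap[1L] - b_long[1L] * b_ap[3L],
             b_long[1L] * b_ap[2L] - b_long[2L] * b_ap[1L])  # z cross x -> y
  basis <- unname(cbind(b_ap, b_mid, b_long))
  out <- mesh
  out$vertices <- unname(vc %*% basis)
  out$aligned <- TRUE
  out
}

#' Humeral length of an aligned mesh
#'
#' Length of the long edge of the axis-aligned bounding box enclosing the
#' aligned model, i.e. the vertex extent along the third (long-axis)
#' coordinate.
#'
#' @param mesh an aligned [bone_surface()] (see
#'   [align_to_standard_position()]).
#' @return length in mm.
#' @export
humeral_length <- function(mesh) {
  stopifnot(inherits(mesh, "bone_surface"))
  if (!mesh$aligned) {
    stop_osteofa("mesh is not aligned; call align_to_standard_position() first")
  }
  z <- mesh$vertices[, 3L]
  hl <- max(z) - min(z)
  if (hl <= 0) stop_osteofa("degenerate mesh: non-positive length")
  hl
}
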