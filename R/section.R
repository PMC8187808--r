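#' Midshaft section contour
#'
#' An ordered closed planar polygon of the periosteal outline in the
#' section plane. In-plane coordinates put the antero-posterior (AP) axis
#' first; vertices are stored counter-clockwise (positive signed area).
#'
#' @param vertices numeric matrix with 2 columns (mm); the closing edge from
#'   the last to the first vertex is implicit.
#' @param plane optional list `(origin, normal)` recording where the section
#'   was cut.
#' @return object of class `section_contour`.
#' @export
section_contour <- function(vertices, plane = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop_osteofa("contour vertices must be 2D")
  if (nrow(vertices) < 3L) stop_osteofa("contour needs at least 3 vertices")
  if (polygon_area(vertices) < 0) {
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  }
  structure(list(vertices = vertices, plane = plane),
            class = "section_contour")
}

#' @export
print.section_contour <- function(x, ...) {
  cat("<section_contour>", nrow(x$vertices), "vertices, area",
      format(polygon_area(x$vertices), digits = 6), "mm^2\n")
  invisible(x)
}

# Shoelace signed area; positive for counter-clockwise polygons.
polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Area centroid of a simple polygon (robust to uneven vertex spacing,
# unlike the vertex mean).
polygon_centroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) stop_osteofa("degenerate polygon")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Extract the midshaft cross-section of an aligned bone mesh
#'
#' Intersects the mesh with the plane perpendicular to the long axis at 50%
#' of the bounding-box extent (the midshaft). The intersection segments are
#' chained edge-by-edge into closed loops; if more than one loop is found
#' (e.g. a detached bony flange at midshaft level) the largest-area loop is
#' kept with a warning. The loop is returned as 2D in-plane coordinates
#' with the AP axis first.
#'
#' @param mesh an aligned [bone_surface()].
#' @param at axial fraction of the bounding box at which to cut
#'   (default 0.5, the midshaft).
#' @return a [section_contour()].
#' @export
extract_midshaft_section <- function(mesh, at = 0.5) {
  stopifnot(inherits(mesh, "bone_surface"))
  if (!mesh$aligned) {
    stop_osteofa("mesh is not aligned; call align_to_standard_position() first")
  }
  z <- mesh$vertices[, 3L]
  z0 <- min(z) + at * (max(z) - min(z))
  d <- z - z0
  # nudge the plane if any vertex lies exactly on it so every intersection
  # is a clean edge crossing
  if (any(d == 0)) {
    eps <- 1e-9 * (max(z) - min(z))
    z0 <- z0 + eps
    d <- z - z0
  }
  loops <- slice_loops(mesh$vertices, mesh$faces, d)
  if (length(loops) == 0L) {
    stop_osteofa("empty intersection: the section plane misses the bone")
  }
  areas <- vapply(loops, function(l) abs(polygon_area(l)), numeric(1))
  if (length(loops) > 1L) {
    warning("midshaft section has ", length(loops),
            " loops; keeping the largest-area loop", call. = FALSE)
  }
  best <- loops[[which.max(areas)]]
  section_contour(best, plane = list(origin = c(0, 0, z0),
                                     normal = c(0, 0, 1)))
}

# Chain plane/triangle intersection segments into closed loops.
# d = signed vertex distance to the plane (no zeros). Intersection points
# sit on mesh edges, so loops are stitched by exact edge identity -- no
# coordinate tolerance needed. Returns a list of n x 2 matrices (x, y).
slice_loops <- function(vertices, faces, d) {
  dv <- matrix(d[faces], ncol = 3L)
  cross <- rowSums(dv > 0) %in% c(1L, 2L)
  if (!any(cross)) return(list())
  f <- faces[cross, , drop = FALSE]
  dvc <- dv[cross, , drop = FALSE]

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")
  pair_a <- cbind(f[, 1L], f[, 2L], f[, 3L])
  pair_b <- cbind(f[, 2L], f[, 3L], f[, 1L])
  crossing <- cbind(dvc[, 1L] * dvc[, 2L] < 0,
                    dvc[, 2L] * dvc[, 3L] < 0,
                    dvc[, 3L] * dvc[, 1L] < 0)
  # each crossing face yields a segment joining its two cut edges
  seg_keys <- t(vapply(seq_len(nrow(f)), function(i) {
    w <- which(crossing[i, ])
    edge_key(pair_a[i, w], pair_b[i, w])
  }, character(2)))

  all_keys <- unique(c(seg_keys))
  # intersection point of each unique cut edge
  split_key <- strsplit(all_keys, "_", fixed = TRUE)
  a_idx <- as.integer(vapply(split_key, `[`, character(1), 1L))
  b_idx <- as.integer(vapply(split_key, `[`, character(1), 2L))
  t_par <- d[a_idx] / (d[a_idx] - d[b_idx])
  pts <- vertices[a_idx, 1:2, drop = FALSE] +
    t_par * (vertices[b_idx, 1:2, drop = FALSE] -
               vertices[a_idx, 1:2, drop = FALSE])
  rownames(pts) <- all_keys

  # adjacency: on a closed manifold each cut edge belongs to exactly two
  # crossing faces, giving each node two neighbours
  nb <- new.env(parent = emptyenv())
  add_nb <- function(k, v) assign(k, c(get0(k, envir = nb), v), envir = nb)
  for (i in seq_len(nrow(seg_keys))) {
    add_nb(seg_keys[i, 1L], seg_keys[i, 2L])
    add_nb(seg_keys[i, 2L], seg_keys[i, 1L])
  }

  visited <- new.env(parent = emptyenv())
  loops <- list()
  for (start in all_keys) {
    if (isTRUE(get0(start, envir = visited))) next
    chain <- character(0)
    prev <- NA_character_
    cur <- start
    repeat {
      chain <- c(chain, cur)
      assign(cur, TRUE, envir = visited)
      nbrs <- get0(cur, envir = nb)
      nxt <- if (is.na(prev)) nbrs[1L] else setdiff(nbrs, prev)[1L]
      if (is.na(nxt) || identical(nxt, start)) break
      prev <- cur
      cur <- nxt
    }
    if (length(chain) >= 3L) {
      loops[[length(loops) + 1L]] <- pts[chain, , drop = FALSE]
    }
  }
  loops
}

#' Reflect a right-side contour for matching bilateral symmetry
#'
#' Left and right bones are mirror images (matching symmetry); before
#' landmark placement the right contour is mirrored across the
#' antero-posterior axis by negating the second in-plane coordinate, and
#' re-wound counter-clockwise. Left contours pass through unchanged, so
#' landmark correspondence between sides is automatic.
#'
#' @param contour a [section_contour()].
#' @param side `"left"` or `"right"`.
#' @return a [section_contour()].
#' @export
reflect_for_matching_symmetry <- function(contour, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(contour, "section_contour"))
  if (side == "left") return(contour)
  v <- contour$vertices
  v[, 2L] <- -v[, 2L]
  section_contour(v, plane = contour$plane)
}

#' Place 16 equiangular radial landmarks on a section contour
#'
#' Casts `k` rays from the area centroid of the contour at equal angular
#' spacing (22.5 degrees for k = 16), ray 1 along the +AP axis, and places
#' one landmark where each ray crosses the periosteal outline. Landmarks 1
#' and 9 therefore span the antero-posterior axis. If a ray crosses the
#' boundary more than once (non-star-shaped contour) the farthest crossing
#' -- the outer periosteal surface -- is used and a warning is issued.
#'
#' @param contour a [section_contour()].
#' @param k number of rays (default 16).
#' @return object of class `landmark_set`: list with `points` (k x 2
#'   matrix, mm) and `centroid`.
#' @export
place_equiangular_landmarks <- function(contour, k = 16L) {
  stopifnot(inherits(contour, "section_contour"))
  v <- contour$vertices
  ctr <- polygon_centroid(v)
  n <- nrow(v)
  p <- sweep(v, 2L, ctr)
  q <- p[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  angles <- (seq_len(k) - 1L) * 2 * pi / k
  multi <- FALSE
  pts <- t(vapply(angles, function(th) {
    dx <- cos(th); dy <- sin(th)
    # ray ctr + t(dx,dy), t >= 0 against each edge p_i -> q_i
    ex <- q[, 1L] - p[, 1L]; ey <- q[, 2L] - p[, 2L]
    den <- dx * ey - dy * ex
    ok <- abs(den) > .Machine$double.eps
    tt <- (p[, 1L] * ey - p[, 2L] * ex) / den
    uu <- (p[, 1L] * dy - p[, 2L] * dx) / den
    # small slack on the edge parameter so a ray through a shared vertex
    # cannot slip between the two adjacent edges under round-off
    hit <- ok & tt > 0 & uu >= -1e-9 & uu < 1
    if (!any(hit)) {
      stop_osteofa("landmark ray at ", round(th * 180 / pi, 1),
                   " deg does not cross the contour (centroid outside?)")
    }
    tmax <- tt[hit]
    if (length(tmax) > 1L &&
        (max(tmax) - min(tmax)) > 1e-9 * max(tmax)) multi <<- TRUE
    t_hit <- max(tmax)
    ctr + t_hit * c(dx, dy)
  }, numeric(2)))
  if (multi) {
    warning("contour is not star-shaped about its centroid; ",
            "using the outermost ray crossings", call. = FALSE)
  }
  structure(list(points = pts, centroid = ctr, k = k),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>", x$k, "equiangular landmarks, centroid (",
      format(x$centroid[1L], digits = 4), ",",
      format(x$centroid[2L], digits = 4), ")\n")
  invisible(x)
}

#' Cortical thickness from equiangular landmarks
#'
#' The periosteal diameter proxy: the mean Euclidean inter-landmark
#' distance over the eight opposite pairs (i, i + 8) that form linear axes
#' through the section (e.g. landmarks 1 and 9 on the antero-posterior
#' axis).
#'
#' @param landmarks a `landmark_set` with 16 points.
#' @return mean diameter in mm.
#' @export
cortical_thickness <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  pts <- landmarks$points
  if (nrow(pts) != 16L) {
    stop_osteofa("cortical_thickness expects 16 landmarks, got ", nrow(pts))
  }
  half <- 8L
  d <- sqrt(rowSums((pts[1:half, , drop = FALSE] -
                       pts[half + (1:half), , drop = FALSE])^2))
  mean(d)
}

#' Measure a left/right bone pair
#'
#' Runs the full measuring protocol on both sides: rigid alignment,
#' bounding-box humeral length, midshaft section extraction, reflection of
#' the right section for matching symmetry, equiangular landmark placement,
#' and cortical thickness. Returns one measurement record per side.
#'
#' @param left,right [bone_surface()] objects of the same specimen.
#' @return data frame with columns `specimen_id`, `species`, `stage`,
#'   `side`, `replicate`, `hl_mm`, `ct_mm`, `source` (two rows).
#' @export
measure_pair <- function(left, right) {
  if (is.null(left) || is.null(right)) {
    stop_osteofa("measure_pair needs both sides")
  }
  stopifnot(inherits(left, "bone_surface"), inherits(right, "bone_surface"))
  if (!identical(left$specimen, right$specimen)) {
    stop_osteofa("left/right meshes have different specimen labels: ",
                 left$specimen, " vs ", right$specimen)
  }
  one <- function(mesh, side) {
    rec <- tryCatch({
      al <- align_to_standard_position(mesh)
      hl <- humeral_length(al)
      sec <- extract_midshaft_section(al)
      sec <- reflect_for_matching_symmetry(sec, side)
      lms <- place_equiangular_landmarks(sec, 16L)
      ct <- cortical_thickness(lms)
      c(hl = hl, ct = ct)
    }, error = function(e) {
      stop_osteofa("measurement failed for specimen ",
                   mesh$specimen %||% "<unknown>", " (", side, " side): ",
                   conditionMessage(e))
    })
    data.frame(
      specimen_id = mesh$specimen, species = mesh$species,
      stage = mesh$stage, side = side, replicate = 1L,
      hl_mm = unname(rec["hl"]), ct_mm = unname(rec["ct"]),
      source = "measured", stringsAsFactors = FALSE
    )
  }
  rbind(one(left, "left"), one(right, "right"))
}
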