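#' Read a paired-measurement CSV
#'
#' Reads and validates a long-format measurement table. Required columns:
#' `specimen_id`, `species`, `stage`, `side`, `replicate`, `hl_mm`,
#' `ct_mm`; an optional `source` column defaults to `"measured"`. Lines
#' starting with `#` (the units header written by
#' [write_measurement_csv()]) are ignored. Validation errors name the
#' offending row.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_measurement_csv <- function(path) {
  if (!file.exists(path)) stop_osteofa("file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_measurement_table(tab, where = path)
}

validate_measurement_table <- function(tab, where = "measurement table") {
  need <- c("specimen_id", "species", "stage", "side", "replicate",
            "hl_mm", "ct_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_osteofa(where, ": missing column: ", paste(miss, collapse = ", "))
  }
  if (!"source" %in% names(tab)) tab$source <- "measured"
  bad_side <- which(!tab$side %in% c("left", "right"))
  if (length(bad_side)) {
    stop_osteofa(where, ": invalid side '", tab$side[bad_side[1L]],
                 "' in row ", bad_side[1L])
  }
  bad_stage <- which(!is.finite(tab$stage) | tab$stage < 1 |
                       tab$stage != round(tab$stage))
  if (length(bad_stage)) {
    stop_osteofa(where, ": invalid stage '", tab$stage[bad_stage[1L]],
                 "' in row ", bad_stage[1L], " (must be integer >= 1)")
  }
  for (col in c("hl_mm", "ct_mm")) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] <= 0)
    if (length(bad)) {
      stop_osteofa(where, ": non-positive ", col, " in row ", bad[1L])
    }
  }
  key <- paste(tab$specimen_id, tab$side, tab$replicate)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_osteofa(where, ": duplicate (specimen_id, side, replicate) key in ",
                 "row ", dup[1L], ": ", key[dup[1L]])
  }
  tab$stage <- as.integer(tab$stage)
  tab$replicate <- as.integer(tab$replicate)
  tab
}

#' Write a measurement table to CSV
#'
#' Writes the long-format table with a `# lengths in mm` units header
#' comment, decimal points and no thousands separators.
#'
#' @param table measurement data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(table, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# osteofa measurement table; lengths in mm", con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read an STL surface file
#'
#' Reads binary or ASCII STL (auto-detected), welds exactly coincident
#' vertices, builds the triangle connectivity and checks that the surface
#' is closed and manifold (every edge shared by exactly two faces).
#'
#' @param path STL file path.
#' @param side `"left"` or `"right"`.
#' @param specimen,species,stage metadata attached to the surface.
#' @param check_manifold error on non-manifold surfaces (default `TRUE`).
#' @return a [bone_surface()].
#' @export
read_stl <- function(path, side = c("left", "right"),
                     specimen = NA_character_, species = NA_character_,
                     stage = NA_integer_, check_manifold = TRUE) {
  side <- match.arg(side)
  if (!file.exists(path)) stop_osteofa("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop_osteofa("STL parse error: ", path,
                                         " is empty or truncated")
  tri <- if (stl_is_ascii(path)) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L || nrow(tri) %% 3L != 0L) {
    stop_osteofa("STL parse error: ", path, " has no complete triangles")
  }
  # weld exactly coincident vertices
  key <- paste(tri[, 1L], tri[, 2L], tri[, 3L], sep = "|")
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  if (any(degen)) faces <- faces[!degen, , drop = FALSE]
  mesh <- bone_surface(verts, faces, side = side, specimen = specimen,
                       species = species, stage = stage)
  if (check_manifold) {
    ok <- mesh_is_manifold(mesh)
    if (!ok) {
      stop_osteofa("non-manifold surface in ", path, ": ",
                   attr(ok, "bad_edges"), " edge(s) not shared by exactly ",
                   "2 faces")
    }
  }
  mesh
}

stl_is_ascii <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  keep <- head >= as.raw(9) & head <= as.raw(126)  # printable ASCII only
  txt <- tolower(rawToChar(head[keep]))
  # binary headers may also start with "solid"; require facet syntax too
  startsWith(trimws(txt), "solid") && grepl("facet", txt, fixed = TRUE)
}

read_stl_binary <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(n_tri) || n_tri <= 0L) {
    stop_osteofa("STL parse error: bad triangle count in ", path)
  }
  expected <- 84 + 50 * as.numeric(n_tri)
  if (file.info(path)$size < expected) {
    stop_osteofa("STL parse error: ", path, " truncated (expected ",
                 expected, " bytes)")
  }
  block <- readBin(con, "raw", n = 50L * n_tri)
  block <- matrix(block, nrow = 50L)
  coords <- block[13:48, , drop = FALSE]  # skip normal (12 bytes), keep 9 floats
  vals <- readBin(as.vector(coords), "numeric", n = 9L * n_tri, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 9L, byrow = TRUE)
  rbind(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE],
        m[, 7:9, drop = FALSE])[order(rep(seq_len(n_tri), 3L)), , drop = FALSE]
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop_osteofa("STL parse error: no vertices in ", path)
  parts <- strsplit(trimws(vl), "\\s+")
  m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(m))) stop_osteofa("STL parse error: bad vertex in ", path)
  m
}

#' Write a mesh as STL
#'
#' @param mesh a [bone_surface()].
#' @param path destination path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  nrm <- cbind(nx, ny, nz)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (format == "binary") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "osteofa binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    tri_vals <- cbind(nrm, p1, p2, p3)  # 12 floats per facet
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri_vals[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("solid osteofa", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1L], nrm[i, 2L],
                nrm[i, 3L]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", p1[i, 1L], p1[i, 2L], p1[i, 3L]),
        sprintf("      vertex %.9g %.9g %.9g", p2[i, 1L], p2[i, 2L], p2[i, 3L]),
        sprintf("      vertex %.9g %.9g %.9g", p3[i, 1L], p3[i, 2L], p3[i, 3L]),
        "    endloop",
        "  endfacet"
      ), con)
    }
    writeLines("endsolid osteofa", con)
  }
  invisible(path)
}

#' Write a section contour or landmark set as CSV for inspection
#'
#' One `x,y` row per point; the plane metadata (if any) is recorded in a
#' `#` header comment. Coordinates in mm.
#'
#' @param obj a `section_contour` or `landmark_set`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(obj, path) {
  pts <- if (inherits(obj, "section_contour")) obj$vertices
         else if (inherits(obj, "landmark_set")) obj$points
         else stop_osteofa("expected a section_contour or landmark_set")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (inherits(obj, "section_contour") && !is.null(obj$plane)) {
    writeLines(sprintf("# plane origin %s normal %s; coordinates in mm",
                       paste(signif(obj$plane$origin, 10), collapse = " "),
                       paste(obj$plane$normal, collapse = " ")), con)
  } else {
    writeLines("# coordinates in mm", con)
  }
  utils::write.csv(data.frame(x = pts[, 1L], y = pts[, 2L]), con,
                   row.names = FALSE)
  invisible(path)
}
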