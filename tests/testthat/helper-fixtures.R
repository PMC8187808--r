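# Independent oracles and small geometric fixtures used across the suite.

# Brute-force two-way balanced crossed ANOVA (cell means decomposition).
# df: columns individual, side, value; balanced with r replicates per cell.
# Independent of the sides_anova() code path (no lm/aov).
oracle_two_way_anova <- function(df) {
  inds <- sort(unique(as.character(df$individual)))
  sides <- sort(unique(as.character(df$side)))
  n <- length(inds)
  s <- length(sides)
  grand <- mean(df$value)
  cell <- matrix(NA_real_, n, s, dimnames = list(inds, sides))
  r <- nrow(df) / (n * s)
  for (i in inds) for (j in sides) {
    cell[i, j] <- mean(df$value[df$individual == i & df$side == j])
  }
  mi <- rowMeans(cell)
  mj <- colMeans(cell)
  ss_ind <- s * r * sum((mi - grand)^2)
  ss_side <- n * r * sum((mj - grand)^2)
  ss_int <- r * sum((cell - outer(mi, rep(1, s)) -
                       outer(rep(1, n), mj) + grand)^2)
  ss_res <- sum((df$value -
                   cell[cbind(as.character(df$individual),
                              as.character(df$side))])^2)
  df_ind <- n - 1
  df_side <- s - 1
  df_int <- (n - 1) * (s - 1)
  df_res <- n * s * (r - 1)
  ms <- c(ss_ind, ss_side, ss_int, ss_res) /
    pmax(c(df_ind, df_side, df_int, df_res), 1)
  list(
    SS = c(individual = ss_ind, side = ss_side, interaction = ss_int,
           residual = ss_res),
    Df = c(df_ind, df_side, df_int, df_res),
    MS = ms,
    F_side = ms[2] / ms[3],
    F_int = if (df_res > 0) ms[3] / ms[4] else NA_real_
  )
}

# Shoelace area of a section_contour (independent of package internals).
polygon_area_for_test <- function(contour) {
  v <- contour$vertices
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Polar radius of an ellipse with semi-axes a (along x) and b.
ellipse_radius <- function(theta, a, b) {
  a * b / sqrt(b^2 * cos(theta)^2 + a^2 * sin(theta)^2)
}

# Closed-form CT oracle for an origin-centred ellipse: mean over the 8
# equiangular axes of the full chord 2 r(theta).
ellipse_ct_oracle <- function(a, b) {
  theta <- (0:7) * pi / 8
  mean(2 * ellipse_radius(theta, a, b))
}

# Rodrigues rotation matrix about unit axis u by angle (radians).
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Watertight unit cube (8 vertices, 12 outward-wound triangles).
cube_mesh <- function(side = "left") {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  bone_surface(v, f, side = side)
}

# Random balanced measurement long table for ANOVA oracle comparisons.
random_sides_table <- function(n_ind, r, seed) {
  set.seed(seed)
  grid <- expand.grid(
    specimen_id = sprintf("i%02d", seq_len(n_ind)),
    side = c("left", "right"),
    replicate = seq_len(r),
    stringsAsFactors = FALSE
  )
  grid$hl_mm <- exp(rnorm(nrow(grid), log(5), 0.3))
  grid$ct_mm <- grid$hl_mm / 10
  grid
}

# Left/right mesh pair with injected size-corrected asymmetries on HL and
# CT, each side rotated by an arbitrary rigid rotation (elliptical
# cross-section so the AP axis is well defined).
mesh_pair_with_asymmetry <- function(hl_true, ct_true, a_hl, a_ct,
                                     aspect = 0.7, n_vertices = 128L,
                                     rot_left = diag(3), rot_right = diag(3),
                                     specimen = "spec") {
  sec <- make_contour("ellipse", list(a = 1, b = aspect), n_vertices)
  # unit-ellipse CT, used to convert the target CT into a section scale
  unit_ct <- ellipse_ct_oracle(1, aspect)
  one <- function(side) {
    sgn <- if (side == "right") 1 else -1
    hl <- hl_true * (1 + sgn * a_hl / 2)
    ct <- ct_true * (1 + sgn * a_ct / 2)
    scale <- ct / unit_ct
    make_bone_mesh(hl, radius_profile = function(t) scale, section = sec,
                   orientation = if (side == "left") rot_left else rot_right,
                   side = side, specimen = specimen)
  }
  list(left = one("left"), right = one("right"))
}
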