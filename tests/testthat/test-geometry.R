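# Elliptical-section cylinder: long axis z, AP (major) axis x, so the
# standard position is well defined (no degenerate principal axes).
ell_cylinder <- function(hl = 10, a = 1, b = 0.6, n_vertices = 128L,
                         orientation = diag(3), side = "left") {
  make_bone_mesh(hl, section = make_contour("ellipse", list(a = a, b = b),
                                            n_vertices),
                 orientation = orientation, side = side)
}

test_that("alignment restores the standard position under rotation", {
  m <- ell_cylinder()
  al <- align_to_standard_position(m)
  expect_true(al$aligned)
  # axis-aligned input: coordinates unchanged up to sign convention
  expect_equal(abs(al$vertices), abs(m$vertices), tolerance = 1e-8)
  expect_equal(humeral_length(al), 10, tolerance = 1e-9)

  # arbitrary known rotation: long axis restored, HL preserved to 1e-6
  rot <- rotation_matrix(c(1, 2, 3), 0.8)
  mr <- ell_cylinder(orientation = rot)
  alr <- align_to_standard_position(mr)
  expect_equal(humeral_length(alr), 10, tolerance = 1e-6)
  # long axis along coordinate 3: z-extent dominates
  expect_equal(diff(range(alr$vertices[, 3])), 10, tolerance = 1e-6)
  expect_lt(diff(range(alr$vertices[, 1])), 2.1)

  # symmetric scatter has no dominant axis
  expect_error(align_to_standard_position(cube_mesh()), "no dominant")
})

test_that("humeral_length demands alignment and scales homogeneously", {
  m <- ell_cylinder()
  expect_error(humeral_length(m), "not aligned")
  al <- align_to_standard_position(m)
  sc <- al
  sc$vertices <- sc$vertices * 3
  expect_equal(humeral_length(sc), 3 * humeral_length(al), tolerance = 1e-12)
})

test_that("midshaft section matches analytic cross-sections", {
  # cylinder r=1: circle of radius 1, perimeter within 0.5% of 2 pi
  cyl <- make_bone_mesh(10, section = make_contour("circle", list(r = 1), 512))
  al <- align_to_standard_position(cyl)
  sec <- extract_midshaft_section(al)
  v <- sec$vertices
  per <- sum(sqrt(rowSums((v - v[c(2:nrow(v), 1), ])^2)))
  expect_lt(abs(per - 2 * pi) / (2 * pi), 0.005)
  expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 0.005)

  # linear frustum radii 1 -> 2 over length 10: midshaft radius 1.5
  fr <- make_bone_mesh(10, radius_profile = function(t) 1 + t,
                       section = make_contour("circle", list(r = 1), 512))
  alf <- align_to_standard_position(fr)
  secf <- extract_midshaft_section(alf)
  rr <- sqrt(rowSums(secf$vertices^2))
  expect_lt(max(abs(rr - 1.5)), 0.01)
})

test_that("multiple section loops keep the largest with a warning", {
  main <- make_bone_mesh(10, section = make_contour("circle", list(r = 1), 64))
  flange <- make_bone_mesh(10, section = make_contour("circle", list(r = 0.2),
                                                      32))
  flange$vertices[, 1] <- flange$vertices[, 1] + 2.5
  combined <- bone_surface(
    rbind(main$vertices, flange$vertices),
    rbind(main$faces, flange$faces + nrow(main$vertices)),
    side = "left", aligned = TRUE
  )
  expect_warning(sec <- extract_midshaft_section(combined), "largest-area")
  # main diaphyseal loop returned (radius ~1 about the origin)
  expect_lt(max(abs(sqrt(rowSums(sec$vertices^2)) - 1)), 0.05)
})

test_that("a plane missing the bone is an error", {
  lower <- make_bone_mesh(2, section = make_contour("circle", list(r = 0.5), 32))
  upper <- make_bone_mesh(2, section = make_contour("circle", list(r = 0.5), 32))
  lower$vertices[, 3] <- lower$vertices[, 3] - 3
  upper$vertices[, 3] <- upper$vertices[, 3] + 3
  gap <- bone_surface(
    rbind(lower$vertices, upper$vertices),
    rbind(lower$faces, upper$faces + nrow(lower$vertices)),
    side = "left", aligned = TRUE
  )
  expect_error(extract_midshaft_section(gap), "misses the bone")
})

test_that("reflection is an involution and a true mirror", {
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  rot10 <- 10 * pi / 180
  # ellipse rotated +10 degrees off-axis
  xy <- cbind(2 * cos(theta), 1 * sin(theta)) %*%
    t(matrix(c(cos(rot10), -sin(rot10), sin(rot10), cos(rot10)), 2, 2,
             byrow = TRUE))
  ct <- section_contour(xy)

  left <- reflect_for_matching_symmetry(ct, "left")
  expect_identical(left$vertices, ct$vertices)

  refl <- reflect_for_matching_symmetry(ct, "right")
  # mirrored ellipse is the ellipse rotated -10 degrees: un-rotating the
  # mirrored vertices by -10 degrees must land on the canonical ellipse
  Rm <- matrix(c(cos(rot10), -sin(rot10), sin(rot10), cos(rot10)), 2, 2,
               byrow = TRUE)
  back <- refl$vertices %*% t(Rm)
  expect_lt(max(abs((back[, 1] / 2)^2 + back[, 2]^2 - 1)), 1e-10)

  twice <- reflect_for_matching_symmetry(refl, "right")
  # involution: same vertex set (order may be rewound)
  expect_equal(sort(twice$vertices[, 1]), sort(ct$vertices[, 1]),
               tolerance = 1e-12)
  expect_equal(sort(twice$vertices[, 2]), sort(ct$vertices[, 2]),
               tolerance = 1e-12)
})

test_that("equiangular landmarks follow the polar-form oracle", {
  circ <- make_contour("circle", list(r = 1), 2048)
  lm <- place_equiangular_landmarks(circ)
  rad <- sqrt(rowSums(lm$points^2))
  expect_equal(rad, rep(1, 16), tolerance = 1e-9)
  ang <- atan2(lm$points[, 2], lm$points[, 1]) %% (2 * pi)
  ang[ang > 2 * pi - 1e-6] <- ang[ang > 2 * pi - 1e-6] - 2 * pi
  expect_equal(sort(ang), (0:15) * pi / 8, tolerance = 1e-9)

  ell <- make_contour("ellipse", list(a = 2, b = 1), 2048)
  lme <- place_equiangular_landmarks(ell)
  theta <- (0:15) * pi / 8
  expect_equal(sqrt(rowSums(lme$points^2)), ellipse_radius(theta, 2, 1),
               tolerance = 1e-5)
  expect_equal(unname(lme$points[1, ]), c(2, 0), tolerance = 1e-9)

  # translation equivariance (centroid-relative construction)
  sh <- section_contour(sweep(ell$vertices, 2, c(-5, -7), "-"))
  lms <- place_equiangular_landmarks(sh)
  expect_equal(lms$points, sweep(lme$points, 2, c(-5, -7), "-"),
               tolerance = 1e-9)
})

test_that("non-star-shaped contours warn and use the outer crossing", {
  # dumbbell: two discs joined by a thin neck; the centroid sits in the
  # neck and the 22.5-degree ray crosses the boundary three times
  arc <- function(cx, from, to, r = 1, n = 60) {
    th <- seq(from, to, length.out = n)
    cbind(cx + r * cos(th), r * sin(th))
  }
  a_j <- asin(0.1)  # neck junction angle on each disc
  poly <- rbind(
    arc(2, -pi + a_j, pi - a_j),    # right disc, CCW through 0
    arc(-2, a_j, 2 * pi - a_j)      # left disc, CCW through pi
  )
  ct <- section_contour(poly)
  expect_warning(lm <- place_equiangular_landmarks(ct), "star-shaped")
  # landmark 2 (22.5 deg) is on the far side of the right disc, not the neck
  expect_gt(sqrt(sum(lm$points[2, ]^2)), 2)
})

test_that("cortical thickness matches closed-form diameters", {
  circ <- make_contour("circle", list(r = 2), 2048)
  expect_equal(cortical_thickness(place_equiangular_landmarks(circ)), 4,
               tolerance = 1e-9)

  ell <- make_contour("ellipse", list(a = 2, b = 1), 2048)
  lme <- place_equiangular_landmarks(ell)
  expect_equal(cortical_thickness(lme), ellipse_ct_oracle(2, 1),
               tolerance = 1e-3 * ellipse_ct_oracle(2, 1))

  # scale equivariance
  sc <- lme
  sc$points <- sc$points * 2.5
  expect_equal(cortical_thickness(sc), 2.5 * cortical_thickness(lme),
               tolerance = 1e-12)

  bad <- place_equiangular_landmarks(circ, k = 8)
  expect_error(cortical_thickness(bad), "16 landmarks")
})

test_that("CT is invariant under 22.5-degree contour rotations", {
  ell <- make_contour("fourier",
                      list(r0 = 1, amplitudes = c(0.1, 0.05, 0.02),
                           phases = c(0.3, 1.1, 2.0)), 2048)
  ct0 <- cortical_thickness(place_equiangular_landmarks(ell))
  for (k in c(1, 3, 8)) {
    th <- k * pi / 8
    rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    rc <- section_contour(ell$vertices %*% t(rot))
    ctk <- cortical_thickness(place_equiangular_landmarks(rc))
    expect_equal(ctk, ct0, tolerance = 1e-9)
  }
})

test_that("HL and CT are rotation and scale invariant end to end", {
  base <- ell_cylinder(hl = 8, a = 0.8, b = 0.5)
  al0 <- align_to_standard_position(base)
  hl0 <- humeral_length(al0)
  ct0 <- cortical_thickness(
    place_equiangular_landmarks(extract_midshaft_section(al0))
  )
  set.seed(31)
  for (i in 1:4) {
    rot <- rotation_matrix(rnorm(3), runif(1, 0.1, 3))
    m <- ell_cylinder(hl = 8, a = 0.8, b = 0.5, orientation = rot)
    al <- align_to_standard_position(m)
    expect_equal(humeral_length(al), hl0, tolerance = 1e-6 * hl0)
    ct <- cortical_thickness(
      place_equiangular_landmarks(extract_midshaft_section(al))
    )
    expect_equal(ct, ct0, tolerance = 1e-6 * ct0)
  }
  # scale equivariance through the full pipeline
  sc <- base
  sc$vertices <- sc$vertices * 3
  als <- align_to_standard_position(sc)
  expect_equal(humeral_length(als), 3 * hl0, tolerance = 1e-9)
  cts <- cortical_thickness(
    place_equiangular_landmarks(extract_midshaft_section(als))
  )
  expect_equal(cts, 3 * ct0, tolerance = 1e-9)
})

test_that("measure_pair recovers truth for mirror and asymmetric pairs", {
  # exact mirror pair: measurements equal to 1e-9
  pair <- mesh_pair_with_asymmetry(6, 0.8, 0, 0, specimen = "s1")
  rec <- measure_pair(pair$left, pair$right)
  expect_equal(rec$hl_mm[1], rec$hl_mm[2], tolerance = 1e-9)
  expect_equal(rec$ct_mm[1], rec$ct_mm[2], tolerance = 1e-9)

  # injected a = 0.04 on HL: recovered within 0.005
  set.seed(5)
  pair2 <- mesh_pair_with_asymmetry(
    6, 0.8, a_hl = 0.04, a_ct = -0.03,
    rot_left = rotation_matrix(rnorm(3), 1.1),
    rot_right = rotation_matrix(rnorm(3), 2.3),
    specimen = "s2"
  )
  rec2 <- measure_pair(pair2$left, pair2$right)
  a_hl <- size_corrected_asymmetry(rec2$hl_mm[rec2$side == "right"],
                                   rec2$hl_mm[rec2$side == "left"])
  a_ct <- size_corrected_asymmetry(rec2$ct_mm[rec2$side == "right"],
                                   rec2$ct_mm[rec2$side == "left"])
  expect_lt(abs(a_hl - 0.04), 0.005)
  expect_lt(abs(a_ct - (-0.03)), 0.005)

  # missing side errors name the specimen
  expect_error(measure_pair(pair$left, NULL), "both sides")
  wrong <- pair2$right
  wrong$specimen <- "other"
  expect_error(measure_pair(pair$left, wrong), "different specimen")
})
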