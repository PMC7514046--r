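test_that("axis-aligned landmarks give the identity frame", {
  lm <- identity_landmarks()
  fr <- build_occlusal_frame(lm$occ, lm$left, lm$right)
  expect_equal(fr$ex, c(1, 0, 0))
  expect_equal(fr$ey, c(0, 1, 0))
  expect_equal(fr$ez, c(0, 0, 1))
  expect_equal(fr$origin, c(0, 0, 0))
})

test_that("frame recovery round-trips under random rigid motions", {
  set.seed(11)
  lm <- identity_landmarks()
  for (i in 1:20) {
    R <- random_rotation()
    tr <- rnorm(3, 0, 20)
    mv <- function(p) as.numeric(R %*% p + tr)
    fr <- build_occlusal_frame(t(apply(lm$occ, 1, mv)), mv(lm$left),
                               mv(lm$right))
    expect_equal(cbind(fr$ex, fr$ey, fr$ez), R, tolerance = 1e-6)
    # transform then recover: arbitrary points return to their start
    pts <- matrix(rnorm(30), 10, 3)
    world <- t(apply(pts, 1, mv))
    expect_equal(to_frame(world, fr), pts, tolerance = 1e-9)
    # and the transform is rigid: pairwise distances preserved
    expect_equal(as.numeric(dist(to_frame(world, fr))),
                 as.numeric(dist(world)), tolerance = 1e-9)
    # inverse transform round-trips
    expect_equal(to_frame(to_frame(world, fr), fr, inverse = TRUE), world,
                 tolerance = 1e-9)
  }
})

test_that("degenerate landmark sets are rejected", {
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(build_occlusal_frame(bad, c(0, 5, 0), c(0, -5, 0)),
               "collinear")
  lm <- identity_landmarks()
  expect_error(build_occlusal_frame(lm$occ, c(1, 2, 3), c(1, 2, 3)),
               "coincide")
})

test_that("posterior reference line runs mesial to distal through the cusps", {
  seg <- make_segment("Mn", "6-7")
  seg$ref_cusps <- rbind(first_molar = c(0, 0, 0),
                         second_molar = c(0, -8, 0))
  rl <- posterior_reference_line(seg)
  expect_equal(rl$direction, c(0, -1, 0))
  expect_equal(rl$point, c(0, 0, 0))
  # default cusps: close to the mesiodistal axis (cusp x offsets differ a
  # little between the two molars)
  d0 <- posterior_reference_line(make_segment("Mn", "6-7"))$direction
  expect_lt(acos(abs(d0[2])), 5 * pi / 180)
  seg$ref_cusps[2, ] <- seg$ref_cusps[1, ]
  expect_error(posterior_reference_line(seg), "coincide")
})

test_that("cusp jitter tilts the reference line within the expected bound", {
  set.seed(5)
  seg <- make_segment("Mn", "6-7")
  base <- posterior_reference_line(seg)$direction
  L <- sqrt(sum((seg$ref_cusps[2, ] - seg$ref_cusps[1, ])^2))
  for (i in 1:25) {
    eps <- 0.3
    segj <- seg
    segj$ref_cusps <- seg$ref_cusps + matrix(runif(6, -eps, eps), 2, 3)
    d <- posterior_reference_line(segj)$direction
    ang <- acos(min(1, sum(d * base)))
    # each endpoint moves < eps*sqrt(3); the chord shortens by < twice that
    bound <- asin(min(1, 2 * eps * sqrt(3) / (L - 2 * eps * sqrt(3))))
    expect_lt(ang, bound)
  }
})

test_that("measurement is invariant to the scene's initial pose", {
  set.seed(21)
  seg <- make_segment("Mn", "5-6", "hypodivergent", jitter_sd = 0.15,
                      seed = 8)
  lm <- identity_landmarks()
  for (angle in c(0, 45)) {
    pl <- place_screw(seg, angle)
    ref <- measure_placement(seg, pl)
    for (i in 1:3) {
      R <- random_rotation()
      tr <- rnorm(3, 0, 15)
      mv <- function(p) as.numeric(R %*% p + tr)
      fr <- build_occlusal_frame(t(apply(lm$occ, 1, mv)), mv(lm$left),
                                 mv(lm$right))
      back <- to_frame(pose_segment(seg, R, tr), fr)
      m <- measure_placement(back, pl)
      expect_equal(m$outcome, ref$outcome)
      expect_equal(m$distance, ref$distance, tolerance = 1e-6)
    }
  }
})

test_that("frame matrix maps frame coordinates to world coordinates", {
  set.seed(3)
  R <- random_rotation()
  lm <- identity_landmarks()
  mv <- function(p) as.numeric(R %*% p + c(1, 2, 3))
  fr <- build_occlusal_frame(t(apply(lm$occ, 1, mv)), mv(lm$left),
                             mv(lm$right))
  M <- frame_matrix(fr)
  p_frame <- c(4, 5, 6)
  expect_equal(as.numeric(M %*% c(p_frame, 1))[1:3],
               to_frame(p_frame, fr, inverse = TRUE), tolerance = 1e-9)
})
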