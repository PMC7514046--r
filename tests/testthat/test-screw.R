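test_that("screw geometry follows the linear radius profile", {
  sc <- build_screw()
  expect_equal(screw_radius(sc, 0), 0.75)
  expect_equal(screw_radius(sc, 6), 0.3)
  expect_equal(screw_radius(sc, 3), 0.525)
  cyl <- build_screw(tip_diameter = 1.5)
  expect_equal(screw_radius(cyl, 4.2), 0.75)
  expect_error(build_screw(tip_diameter = 2), "exceed")
  expect_error(build_screw(length = 0), "positive")
})

test_that("initial placement follows the protocol on a flat sheet", {
  for (jaw in c("Mx", "Mn")) {
    seg <- cylinder_segment(jaw = jaw)
    pl <- initial_placement(seg, build_screw())
    apical <- seg$apical_dir
    # 4 mm apical to the CEJ, on the sheet, at the mesiodistal midpoint
    expect_equal(pl$insertion_point[3], seg$cej_z + 4 * apical)
    expect_equal(pl$insertion_point[1], seg$bone$x_buccal)
    expect_equal(pl$insertion_point[2], 0) # symmetric cylinders
    expect_equal(pl$axis, c(-1, 0, 0))
    expect_equal(pl$angle, 0)
    expect_equal(pl$neck_point, pl$insertion_point)
    expect_equal(pl$apex_point, pl$insertion_point + c(-6, 0, 0))
  }
})

test_that("angulation rotates vertically about the insertion point", {
  seg <- cylinder_segment(jaw = "Mx")
  p0 <- initial_placement(seg, build_screw())
  expect_identical(angulate(p0, 0, seg), p0)
  p60 <- angulate(p0, 60, seg)
  expect_equal(p60$apex_point[3] - p60$neck_point[3], 6 * sin(pi / 3),
               tolerance = 1e-12)
  expect_equal(p60$neck_point[1] - p60$apex_point[1], 6 * cos(pi / 3),
               tolerance = 1e-12)
  p45 <- angulate(p0, 45, seg)
  expect_equal(p45$neck_point[1] - p45$apex_point[1], 6 * cos(pi / 4),
               tolerance = 1e-12)
  # mandible: tip apical means downward
  segm <- cylinder_segment(jaw = "Mn")
  q60 <- place_screw(segm, 60)
  expect_lt(q60$apex_point[3], q60$neck_point[3])
  # shank length is preserved
  expect_equal(sqrt(sum((p60$apex_point - p60$neck_point)^2)), 6)
  expect_error(angulate(p0, 95, seg), "angle")
})

test_that("the mesiodistal midpoint is preserved at every angle", {
  seg <- make_segment("Mn", "6-7", "hypodivergent", jitter_sd = 0.2, seed = 2)
  p0 <- initial_placement(seg, build_screw())
  for (a in c(0, 30, 45, 60)) {
    pl <- angulate(p0, a, seg)
    expect_identical(pl$neck_point[2], p0$insertion_point[2])
    expect_identical(pl$apex_point[2], p0$insertion_point[2])
    # axis-plane angle equals the requested insertion angle
    expect_equal(asin(abs(pl$axis[3])) * 180 / pi, a, tolerance = 1e-9)
    # neck stays on the cortical sheet
    expect_equal(pl$neck_point[1],
                 miniscrewsim:::sheet_x(seg, pl$neck_point[3]),
                 tolerance = 1e-9)
  }
})

test_that("the in-bone check detects each exit mode", {
  seg <- cylinder_segment()
  pl <- place_screw(seg, 0)
  expect_true(check_in_bone(pl, seg)$pass)
  # sheet moved lingual of the apex: shank emerges buccally
  seg_b <- seg
  seg_b$bone$x_buccal <- pl$apex_point[1] - 1
  expect_match(check_in_bone(pl, seg_b)$reason, "buccal")
  # lingual cortex moved onto the apex
  seg_l <- seg
  seg_l$bone$lingual_x <- pl$apex_point[1] + 1
  expect_match(check_in_bone(pl, seg_l)$reason, "lingual")
  # shallow apical bone stock: the sampled check agrees with the analytic
  # exit condition 4 + 6*sin(angle) > apical_extent
  seg60 <- cylinder_segment()
  p60 <- place_screw(seg60, 60)
  seg_s <- seg60
  seg_s$bone$apical_extent <- 9.1   # apex depth 4 + 6 sin 60 = 9.196
  expect_match(check_in_bone(p60, seg_s)$reason, "apical")
  p45 <- place_screw(seg60, 45)     # apex depth 8.243 < 9.1
  expect_true(check_in_bone(p45, seg_s)$pass)
  # constructors refuse placements that fail the check
  expect_error(place_screw(seg_s, 60), "in-bone")
})
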