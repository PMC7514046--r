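test_that("slice distance matches the collinear-circles closed form", {
  # vertical cylindrical screw (circular section, r 0.75) at the origin,
  # circular root section (r 1) centered 3 mm mesially, u = mesiodistal:
  # gap = 3 - 1 - 0.75 = 1.25
  root <- make_root(c(0, 3, 0), c(0, 0, 1), 14, 1, 1)
  post <- make_root(c(0, -6, 0), c(0, 0, 1), 14, 1, 1)
  seg <- manual_segment(root, post)
  pl <- manual_placement(c(0, 0, 2), c(0, 0, 1),
                         build_screw(6, 1.5, 1.5))
  expect_equal(slice_distance(seg, pl, 5), 1.25, tolerance = 1e-9)
  expect_equal(slice_distance(seg, pl, 2.0), 1.25, tolerance = 1e-9)
  expect_error(slice_distance(seg, pl, 1), "span")
  # screw buccal to the corridor: disjoint buccolingual intervals
  pl_b <- manual_placement(c(5, 0, 2), c(0, 0, 1), build_screw(6, 1.5, 1.5))
  expect_true(is.na(slice_distance(seg, pl_b, 5)))
})

test_that("slice distance agrees with a 10x-resolution evaluation", {
  set.seed(4)
  for (i in 1:10) {
    seg <- make_segment(sample(c("Mx", "Mn"), 1), sample(c("5-6", "6-7"), 1),
                        jitter_sd = 0.2, seed = i)
    pl <- try(place_screw(seg, sample(c(30, 45, 60), 1)), silent = TRUE)
    if (inherits(pl, "try-error")) next
    z <- mean(c(pl$neck_point[3], pl$apex_point[3]))
    d1 <- slice_distance(seg, pl, z, v_step = 0.05)
    d2 <- slice_distance(seg, pl, z, v_step = 0.005)
    if (is.na(d1)) expect_true(is.na(d2)) else
      expect_equal(d1, d2, tolerance = 1e-3)
  }
})

test_that("cylinder scene at 0 degrees gives the exact planar gap", {
  seg <- cylinder_segment(gap = 3.4, r_md = 2, r_bl = 3)
  pl <- place_screw(seg, 0, build_screw(6, 1.5, 1.5))
  m <- measure_placement(seg, pl)
  # by translational symmetry: distance = width/2 - screw radius
  expect_equal(m$distance, 3.4 / 2 - 0.75, tolerance = 1e-9)
  expect_equal(m$outcome, "measurable")
  # single slice at the screw height
  expect_equal(m$argmin_z, pl$neck_point[3])
})

test_that("halving the slice thickness never increases the minimum", {
  set.seed(9)
  for (i in 1:6) {
    seg <- make_segment(sample(c("Mx", "Mn"), 1), "5-6", jitter_sd = 0.2,
                        seed = 30 + i)
    pl <- try(place_screw(seg, sample(c(30, 45, 60), 1)), silent = TRUE)
    if (inherits(pl, "try-error")) next
    d1 <- measure_placement(seg, pl, slice_thickness = 0.2)
    d2 <- measure_placement(seg, pl, slice_thickness = 0.1)
    d3 <- measure_placement(seg, pl, slice_thickness = 0.05)
    if (d1$outcome == "measurable" && d3$outcome == "measurable") {
      expect_lte(d2$distance, d1$distance + 1e-9)
      expect_lte(d3$distance, d2$distance + 1e-9)
    }
  }
})

test_that("distance is non-decreasing in angle for monotone-width segments", {
  for (spec in list(c("Mx", "5-6"), c("Mn", "5-6"), c("Mn", "6-7"))) {
    seg <- make_segment(spec[1], spec[2])
    d <- vapply(c(0, 30, 45, 60), function(a) {
      m <- measure_placement(seg, place_screw(seg, a))
      if (m$outcome == "measurable") m$distance else Inf
    }, numeric(1))
    expect_true(all(diff(d) >= -1e-9), info = paste(spec, collapse = " "))
  }
})

test_that("the default Mx 6-7 profile yields the 30-degree dip", {
  seg <- make_segment("Mx", "6-7")
  d <- vapply(c(0, 30, 45, 60), function(a)
    measure_placement(seg, place_screw(seg, a))$distance, numeric(1))
  expect_lt(d[2], d[1])   # 30 below 0
  expect_gt(d[3], d[2])   # 45 above 30
  expect_gt(d[4], d[2])   # 60 above 30
})

test_that("noncontact is returned when the corridor is missed at all slices", {
  # very thick ridge pushes the angulated screw buccal of a short root
  seg <- make_segment("Mn", "5-6", overrides = list(
    ridge_offset = 3,
    anterior = list(label = "5", length = 10, semi_md = 2.2, semi_bl = 3.2,
                    taper = 0.5, bow = 0)))
  m <- measure_placement(seg, place_screw(seg, 60))
  expect_equal(m$outcome, "noncontact")
  expect_true(is.na(m$distance))
})

test_that("contact detection: pigeonhole, midway and tangency cases", {
  # corridor narrower than the screw diameter -> contact
  seg_thin <- cylinder_segment(gap = 1.2)
  pl <- manual_placement(c(seg_thin$bone$x_buccal, 0, -4), c(-1, 0, 0),
                         build_screw(6, 1.5, 1.5))
  expect_true(detect_contact(seg_thin, pl))
  expect_equal(measure_placement(seg_thin, pl)$outcome, "contact")
  # screw midway in a 4 mm corridor -> no contact
  seg_wide <- cylinder_segment(gap = 4)
  pl_w <- place_screw(seg_wide, 0)
  expect_false(detect_contact(seg_wide, pl_w))
  # constructed tangency: corridor width equals the cylinder diameter
  seg_t <- cylinder_segment(gap = 1.5)
  pl_t <- manual_placement(c(seg_t$bone$x_buccal, 0, -4), c(-1, 0, 0),
                           build_screw(6, 1.5, 1.5))
  ct <- detect_contact(seg_t, pl_t)
  expect_true(ct)
  expect_lt(abs(attr(ct, "clearance")), 1e-6)
})

test_that("analytic measurement agrees with the brute-force oracle", {
  n_ok <- 0
  for (i in 1:12) {
    seg <- try(make_segment(c("Mx", "Mn")[1 + i %% 2],
                            c("5-6", "6-7")[1 + (i %/% 2) %% 2],
                            facial_groups()[1 + i %% 3],
                            jitter_sd = 0.25, seed = 100 + i), silent = TRUE)
    if (inherits(seg, "try-error")) next
    pl <- try(place_screw(seg, c(0, 30, 45, 60)[1 + i %% 4]), silent = TRUE)
    if (inherits(pl, "try-error")) next
    m <- measure_placement(seg, pl)
    b <- brute_force_distance(seg, pl, n_samples = 800, seed = i)
    expect_equal(b$outcome, m$outcome)
    if (m$outcome == "measurable" && b$outcome == "measurable") {
      expect_equal(b$distance, m$distance, tolerance = 1e-3)
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok, 6)
})

test_that("oracle minima are monotone under sample doubling", {
  seg <- make_segment("Mn", "6-7", jitter_sd = 0.2, seed = 55)
  for (a in c(0, 45)) {
    pl <- place_screw(seg, a)
    d <- vapply(c(200, 400, 800, 1600), function(n)
      brute_force_distance(seg, pl, n, seed = 7)$distance, numeric(1))
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("oracle classifies contact scenes as contact", {
  seg_thin <- cylinder_segment(gap = 1.2)
  pl <- manual_placement(c(seg_thin$bone$x_buccal, 0, -4), c(-1, 0, 0),
                         build_screw(6, 1.5, 1.5))
  expect_equal(brute_force_distance(seg_thin, pl, 400, 1)$outcome, "contact")
})

test_that("ties in the slice minimum report the most cervical slice", {
  # cylinder roots + cylinder screw at 45 degrees: among the slices cutting
  # the full shank the gap is constant, so the reported argmin must be the
  # most cervical (closest to the CEJ) of the tied slices
  seg <- cylinder_segment(gap = 4, jaw = "Mx")
  pl <- place_screw(seg, 45, build_screw(6, 1.5, 1.5))
  m <- measure_placement(seg, pl)
  zs <- miniscrewsim:::slice_grid(pl, 0.1)
  per_slice <- vapply(zs, function(z) {
    d <- slice_distance(seg, pl, z)
    if (is.na(d)) Inf else d
  }, numeric(1))
  tied <- zs[per_slice <= min(per_slice) + 1e-9]
  expect_equal(m$argmin_z, tied[which.min(seg$apical_dir * (tied - seg$cej_z))])
})
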