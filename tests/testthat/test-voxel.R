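test_that("voxelized cylinder sections have the right area", {
  seg <- cylinder_segment(gap = 3, r_md = 2, r_bl = 2)
  vol <- voxelize_segment(seg, voxel_size = 0.1)
  # pick an axial layer at 5 mm depth: each root section is a 2 mm circle
  zs <- vol$origin[3] + (seq_len(dim(vol$arr)[3]) - 1) * vol$voxel_size
  k <- which.min(abs(zs - (seg$cej_z - 5)))
  area <- sum(vol$arr[, , k] == 2) * vol$voxel_size^2
  expect_lt(abs(area - pi * 2^2) / (pi * 4), 0.05)
})

test_that("label boundaries stay within a voxel diagonal of the surface", {
  seg <- make_segment("Mn", "6-7")
  vol <- voxelize_segment(seg, voxel_size = 0.1)
  bp <- label_boundary_points(vol, 2)
  # compare against the lateral tube: drop boundary voxels on the flat
  # cervical/apical end discs, which root_surface_points does not sample
  root <- seg$anterior$roots[[1]]
  depth <- seg$apical_dir * (bp[, 3] - root$cej_center[3])
  bp <- bp[depth > 0.15 & depth < root$length - 0.15, , drop = FALSE]
  set.seed(2)
  bp <- bp[sample(nrow(bp), 250), ]
  surf <- root_surface_points(root, n_depth = 160, n_theta = 250)
  dmin <- vapply(seq_len(nrow(bp)), function(i) {
    sqrt(min(colSums((t(surf) - bp[i, ])^2)))
  }, numeric(1))
  expect_lt(max(dmin), sqrt(3) * vol$voxel_size)
})

test_that("empty scenes voxelize to background and error downstream", {
  bbox <- rbind(c(0, 0, 0), c(2, 2, 2))
  vol <- voxelize_segment(NULL, voxel_size = 0.2, bbox = bbox)
  expect_true(all(vol$arr == 0L))
  pl <- manual_placement(c(1, 1, 1), c(-1, 0, 0))
  expect_error(voxel_measure(vol, pl), "screw")
})

test_that("coarse voxels trigger the resolution warning", {
  seg <- cylinder_segment(gap = 2)
  expect_warning(voxelize_segment(seg, voxel_size = 2.5), "resolution|gap")
})

test_that("screw rasterization matches the frustum volume", {
  seg <- cylinder_segment(gap = 4)
  pl <- place_screw(seg, 30)
  vol <- rasterize_screw(voxelize_segment(seg, 0.1), pl)
  sc <- pl$screw
  v_analytic <- pi * sc$length / 3 *
    (sc$r_neck^2 + sc$r_neck * sc$r_tip + sc$r_tip^2)
  v_vox <- sum(vol$arr == 4L) * 0.1^3
  expect_lt(abs(v_vox - v_analytic) / v_analytic, 0.1)
})

test_that("voxel measurement tracks the analytic measurement", {
  for (i in 1:3) {
    seg <- make_segment(c("Mx", "Mn")[1 + i %% 2], "5-6",
                        jitter_sd = 0.2, seed = 200 + i)
    pl <- place_screw(seg, c(0, 30, 45)[i])
    m <- measure_placement(seg, pl)
    vol <- rasterize_screw(voxelize_segment(seg, 0.1), pl)
    vm <- voxel_measure(vol, pl, segment = seg)
    expect_equal(vm$outcome, m$outcome)
    if (m$outcome == "measurable")
      expect_lt(abs(vm$distance - m$distance), 2 * sqrt(3) * 0.1)
  }
})

test_that("NIfTI export round-trips", {
  seg <- cylinder_segment()
  vol <- voxelize_segment(seg, voxel_size = 0.4)
  for (ext in c(".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_nifti(vol, f)
    back <- read_nifti(f)
    expect_identical(back$arr, vol$arr)
    expect_equal(back$origin, vol$origin, tolerance = 1e-6)
    expect_equal(back$voxel_size, vol$voxel_size, tolerance = 1e-6)
    expect_true(file.exists(sub("\\.nii(\\.gz)?$", ".labels.json", f)))
  }
})
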