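#' Voxelize a segment into a labeled volume
#'
#' Rasterizes the analytic scene onto a regular grid (voxel-center tests):
#' 0 background, 1 bone, 2 anterior root, 3 posterior root (roots override
#' bone). The volume is axis-aligned with the standardized frame.
#'
#' @param segment a [make_segment()] object, or `NULL` for an empty scene
#'   (then `bbox` is required)
#' @param voxel_size isotropic voxel edge, mm
#' @param margin padding around the scene bounding box, mm
#' @param bbox optional 2x3 matrix (min/max rows) overriding the bounding box
#' @return object of class `label_volume`: integer array `arr`, `origin`
#'   (center of voxel \[1,1,1\]), `voxel_size`, `legend`
#' @export
voxelize_segment <- function(segment, voxel_size = 0.1, margin = 1,
                             bbox = NULL) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (is.null(bbox)) {
    if (is.null(segment)) stop("either a segment or a bbox is required")
    roots <- c(segment$anterior$roots, segment$posterior$roots)
    rx <- range(unlist(lapply(roots, function(r)
      r$cej_center[1] + c(-1, 1) * r$semi_axis_bl)))
    ry <- range(unlist(lapply(roots, function(r)
      r$cej_center[2] + c(-1, 1) * (r$semi_axis_md + abs(r$bow)))))
    rz <- range(unlist(lapply(roots, function(r)
      c(r$cej_center[3], r$cej_center[3] + r$axis[3] * r$length))))
    bbox <- rbind(c(rx[1], ry[1], rz[1]) - margin,
                  c(max(rx[2], segment$bone$x_buccal), ry[2], rz[2]) + margin)
  }
  if (!is.null(segment) && voxel_size > segment$params$gap_cej)
    warning("voxel size exceeds the interradicular gap at the CEJ; ",
            "the corridor cannot be resolved")
  xs <- seq(bbox[1, 1] + voxel_size / 2, bbox[2, 1], by = voxel_size)
  ys <- seq(bbox[1, 2] + voxel_size / 2, bbox[2, 2], by = voxel_size)
  zs <- seq(bbox[1, 3] + voxel_size / 2, bbox[2, 3], by = voxel_size)
  arr <- array(0L, c(length(xs), length(ys), length(zs)))
  if (!is.null(segment)) {
    for (k in seq_along(zs)) {
      z <- zs[k]
      depth <- segment$apical_dir * (z - segment$cej_z)
      lab <- matrix(0L, length(xs), length(ys))
      if (depth >= segment$bone$crest_depth &&
          depth <= segment$bone$apical_extent) {
        in_bone <- xs <= sheet_x(segment, z) & xs >= segment$bone$lingual_x
        lab[in_bone, ] <- 1L
      }
      for (side in c("anterior", "posterior")) {
        code <- if (side == "anterior") 2L else 3L
        for (r in segment[[side]]$roots) {
          s <- root_section(r, z)
          if (is.null(s)) next
          inside <- outer(((xs - s$cx) / s$bx)^2, ((ys - s$cy) / s$ay)^2,
                          `+`) <= 1
          lab[inside] <- code
        }
      }
      arr[, , k] <- lab
    }
  }
  structure(list(arr = arr, origin = c(xs[1], ys[1], zs[1]),
                 voxel_size = voxel_size,
                 legend = c(background = 0, bone = 1, anterior_root = 2,
                            posterior_root = 3, screw = 4)),
            class = "label_volume")
}

#' Rasterize a screw placement into a labeled volume
#'
#' Labels voxels whose centers fall inside the screw solid with code 4.
#'
#' @param volume a [voxelize_segment()] result
#' @param placement a [place_screw()] object
#' @return the updated `label_volume`
#' @export
rasterize_screw <- function(volume, placement) {
  vs <- volume$voxel_size
  dm <- dim(volume$arr)
  ax <- placement$axis
  nk <- placement$neck_point
  sc <- placement$screw
  co <- function(i, d) volume$origin[d] + (i - 1) * vs
  ## restrict to the screw bounding box
  lo <- pmin(nk, placement$apex_point) - sc$r_neck
  hi <- pmax(nk, placement$apex_point) + sc$r_neck
  ix <- which(co(seq_len(dm[1]), 1) >= lo[1] & co(seq_len(dm[1]), 1) <= hi[1])
  iy <- which(co(seq_len(dm[2]), 2) >= lo[2] & co(seq_len(dm[2]), 2) <= hi[2])
  iz <- which(co(seq_len(dm[3]), 3) >= lo[3] & co(seq_len(dm[3]), 3) <= hi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(volume)
  g <- expand.grid(x = co(ix, 1), y = co(iy, 2), z = co(iz, 3))
  d <- cbind(g$x - nk[1], g$y - nk[2], g$z - nk[3])
  s <- d %*% ax
  rad2 <- rowSums(d^2) - s^2
  inside <- s >= 0 & s <= sc$length & rad2 <= screw_radius(sc, s)^2
  sub <- array(volume$arr[ix, iy, iz], c(length(ix), length(iy), length(iz)))
  sub[array(inside, dim(sub))] <- 4L
  volume$arr[ix, iy, iz] <- sub
  volume
}

#' Voxel-domain miniscrew-root distance
#'
#' Image-domain counterpart of [measure_placement()]: within each axial
#' voxel layer between the apex and the neck, rows parallel to the
#' mesiodistal grid axis are scanned; the gap is the count of voxels
#' strictly between the screw label and the anterior-root label times the
#' voxel size, minimized over rows and layers. A layer with no row
#' containing both labels contributes no overlap; if no layer overlaps the
#' outcome is `"noncontact"`, and touching/overlapping labels give
#' `"contact"`.
#'
#' @param volume a labeled volume with the screw rasterized in place
#' @param placement the corresponding `screw_placement`
#' @param segment optional segment; when given, the reference-line direction
#'   is checked to be mesiodistal (the voxel scan direction)
#' @param subject_id optional identifier
#' @return a `measurement_record`
#' @export
voxel_measure <- function(volume, placement, segment = NULL,
                          subject_id = NA_character_) {
  arr <- volume$arr
  if (!any(arr == 4L)) stop("volume lacks a rasterized screw (label 4)")
  if (!any(arr == 2L)) stop("volume lacks an anterior root (label 2)")
  if (!is.null(segment)) {
    u <- posterior_reference_line(segment)$direction
    if (abs(u[2]) < cos(25 * pi / 180))
      stop("reference line is not aligned with the mesiodistal voxel axis")
  }
  vs <- volume$voxel_size
  zs <- volume$origin[3] + (seq_len(dim(arr)[3]) - 1) * vs
  z1 <- min(placement$neck_point[3], placement$apex_point[3])
  z2 <- max(placement$neck_point[3], placement$apex_point[3])
  layers <- which(zs >= z1 - vs / 2 & zs <= z2 + vs / 2)
  jaw <- if (!is.null(segment)) segment$jaw else NA_character_
  rec <- function(outcome, distance = NA_real_, argmin_z = NA_real_) {
    structure(list(subject_id = subject_id, jaw = jaw,
                   site = if (!is.null(segment)) segment$site else NA_character_,
                   side = if (!is.null(segment)) segment$side else NA_character_,
                   angle = placement$angle, outcome = outcome,
                   distance = distance, argmin_z = argmin_z),
              class = "measurement_record")
  }
  best <- Inf; best_z <- NA_real_; any_overlap <- FALSE
  for (k in layers) {
    M <- arr[, , k]
    scr <- M == 4L
    rt <- M == 2L
    rows <- which(apply(scr, 1, any) & apply(rt, 1, any))
    if (!length(rows)) next
    any_overlap <- TRUE
    for (i in rows) {
      ## anterior root is mesial (+y): gap counted from the screw's highest
      ## y index to the root's lowest y index above it
      ys_s <- which(scr[i, ])
      ys_r <- which(rt[i, ])
      gap_vox <- min(ys_r) - max(ys_s) - 1L
      g <- gap_vox * vs
      if (g < best) { best <- g; best_z <- zs[k] }
    }
  }
  if (!any_overlap) return(rec("noncontact"))
  if (best <= 0) return(rec("contact"))
  rec("measurable", best, best_z)
}

#' Boundary voxel centers of a label
#'
#' Centers of voxels carrying `label` that touch (6-neighborhood) a voxel
#' with a different label; used to compare rasterized surfaces with their
#' analytic counterparts.
#'
#' @param volume a `label_volume`
#' @param label integer label code
#' @return n x 3 matrix of voxel-center coordinates
#' @export
label_boundary_points <- function(volume, label) {
  a <- volume$arr == label
  d <- dim(a)
  shift <- function(a, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- (1:d[1]) - dx; ys <- (1:d[2]) - dy; zs <- (1:d[3]) - dz
    ok_x <- xs >= 1 & xs <= d[1]
    ok_y <- ys >= 1 & ys <= d[2]
    ok_z <- zs >= 1 & zs <= d[3]
    out[ok_x, ok_y, ok_z] <- a[xs[ok_x], ys[ok_y], zs[ok_z]]
    out
  }
  nb <- shift(a, 1, 0, 0) & shift(a, -1, 0, 0) &
        shift(a, 0, 1, 0) & shift(a, 0, -1, 0) &
        shift(a, 0, 0, 1) & shift(a, 0, 0, -1)
  boundary <- a & !nb
  idx <- which(boundary, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, rep(volume$voxel_size, 3), `*`), 2,
        volume$origin, `+`)
}
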