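#' Detect screw-root contact
#'
#' `TRUE` when the screw solid touches or intersects the root surface of
#' either adjacent tooth (minimum signed clearance at most `tol`).
#' Clearances are evaluated on a dense (slice x offset) grid covering the
#' full vertical extent of the solid, with two local refinement passes
#' around the minimizing cell.
#'
#' @param segment a [make_segment()] object
#' @param placement a [place_screw()] object
#' @param z_step,v_step sampling steps, mm
#' @param tol contact tolerance, mm
#' @return logical; attribute `"clearance"` carries the minimum clearance
#' @export
detect_contact <- function(segment, placement, z_step = 0.05, v_step = 0.05,
                           tol = 1e-6) {
  basis <- measurement_basis(segment, placement)
  r0 <- placement$screw$r_neck
  z1 <- min(placement$neck_point[3], placement$apex_point[3]) - r0 - z_step
  z2 <- max(placement$neck_point[3], placement$apex_point[3]) + r0 + z_step
  one_side <- function(side, zs, vs, refine) {
    Z <- seq(z1, z2, by = zs)
    roots <- segment[[side]]$roots
    rv <- root_v_range(roots, Z, basis)
    sv <- screw_v_range(placement, basis)
    lo <- max(rv[1], sv[1]) - 2 * vs
    hi <- min(rv[2], sv[2]) + 2 * vs
    if (!is.finite(lo) || !is.finite(hi) || lo > hi) return(Inf)
    V <- seq(lo, hi, by = vs)
    cg <- clearance_grid(segment, placement, Z, V, basis, roots, side)
    if (!any(cg$both)) return(Inf)
    m <- which(cg$gap == min(cg$gap, na.rm = TRUE), arr.ind = TRUE)[1, ]
    cur <- min(cg$gap, na.rm = TRUE)
    if (!refine) return(cur)
    ## two local refinement rounds (z and v jointly)
    zc <- Z[m[1]]; vc <- V[m[2]]; dz <- zs; dv <- vs
    for (round in 1:2) {
      Zf <- seq(zc - dz, zc + dz, length.out = 21)
      Vf <- seq(vc - dv, vc + dv, length.out = 21)
      cf <- clearance_grid(segment, placement, Zf, Vf, basis, roots, side)
      if (any(cf$both)) {
        mf <- which(cf$gap == min(cf$gap, na.rm = TRUE), arr.ind = TRUE)[1, ]
        cur <- min(cur, min(cf$gap, na.rm = TRUE))
        zc <- Zf[mf[1]]; vc <- Vf[mf[2]]
      }
      dz <- dz / 10; dv <- dv / 10
    }
    cur
  }
  best <- Inf
  for (side in c("anterior", "posterior")) {
    ## coarse screen first: clearance varies smoothly (surface slopes are
    ## O(1)), so a coarse minimum well above zero rules out contact
    coarse <- one_side(side, z_step * 5, v_step * 3, refine = FALSE)
    if (coarse > 0.35) { best <- min(best, coarse); next }
    best <- min(best, one_side(side, z_step, v_step, refine = TRUE))
  }
  structure(best <= tol, clearance = best)
}

#' Directional screw-root distance in one axial slice
#'
#' Implements the per-slice measurement rule: among the buccolingual
#' offsets covered by both the screw cross-section and the anterior root
#' cross-section, the smallest gap from the mesial boundary of the screw to
#' the distal boundary of the root, measured parallel to the posterior
#' reference line. Returns `NA` (no overlap) when the two sections share no
#' buccolingual offset or the root does not reach the slice - the screw is
#' buccally outside the root distalization corridor at this level.
#'
#' @param segment a [make_segment()] object
#' @param placement a [place_screw()] object
#' @param z slice height, mm (must lie within the apex-neck span)
#' @param v_step offset resolution, mm
#' @param refine locally refine around the minimizing offset
#' @return gap in mm, or `NA_real_` for no overlap
#' @export
slice_distance <- function(segment, placement, z, v_step = 0.05,
                           refine = TRUE) {
  z1 <- min(placement$neck_point[3], placement$apex_point[3])
  z2 <- max(placement$neck_point[3], placement$apex_point[3])
  if (z < z1 - 1e-9 || z > z2 + 1e-9)
    stop("slice height lies outside the apex-neck span")
  basis <- measurement_basis(segment, placement)
  roots <- segment$anterior$roots
  sv <- screw_v_range(placement, basis)
  rv <- root_v_range(roots, z, basis)
  lo <- min(sv[1], rv[1], na.rm = TRUE)
  hi <- max(sv[2], rv[2], na.rm = TRUE)
  V <- seq(lo - v_step, hi + v_step, by = v_step)
  sm <- slice_minima(segment, placement, z, V, basis, roots,
                     refine = refine)
  if (!any(sm$screw_any))
    stop("screw cross-section is empty at this slice height")
  if (is.finite(sm$min)) sm$min else NA_real_
}

#' Measure the miniscrew-root distance for one placement
#'
#' The full measurement rule: if the screw contacts a root at insertion the
#' outcome is `"contact"`. Otherwise the directional gap is evaluated on
#' axial slices of `slice_thickness` (default 0.1 mm) between the apex and
#' the neck (both ends included); the smallest per-slice gap is the
#' miniscrew-root distance. If every slice shows no buccolingual overlap
#' with the anterior root's corridor the outcome is `"noncontact"` (the
#' screw cannot obstruct root distalization). Ties across slices report the
#' most cervical minimizing slice.
#'
#' @param segment a [make_segment()] object, standardized frame
#' @param placement a [place_screw()] object for that segment
#' @param slice_thickness axial slice spacing, mm
#' @param v_step buccolingual offset resolution, mm
#' @param refine locally refine per-slice minima
#' @param contact_tol contact tolerance, mm
#' @param subject_id optional identifier carried into the record
#' @return object of class `measurement_record`: fields `subject_id`, `jaw`,
#'   `site`, `side`, `angle`, `outcome` (`"measurable"`, `"contact"`,
#'   `"noncontact"`), `distance` (mm, `NA` unless measurable), `argmin_z`
#' @export
measure_placement <- function(segment, placement, slice_thickness = 0.1,
                              v_step = 0.05, refine = TRUE,
                              contact_tol = 1e-6, subject_id = NA_character_) {
  rec <- function(outcome, distance = NA_real_, argmin_z = NA_real_) {
    structure(list(subject_id = subject_id, jaw = segment$jaw,
                   site = segment$site, side = segment$side,
                   angle = placement$angle, outcome = outcome,
                   distance = distance, argmin_z = argmin_z),
              class = "measurement_record")
  }
  if (isTRUE(detect_contact(segment, placement, tol = contact_tol)))
    return(rec("contact"))
  basis <- measurement_basis(segment, placement)
  roots <- segment$anterior$roots
  Z <- slice_grid(placement, slice_thickness)
  rv <- root_v_range(roots, Z, basis)
  sv <- screw_v_range(placement, basis)
  lo <- max(rv[1], sv[1]) - 2 * v_step
  hi <- min(rv[2], sv[2]) + 2 * v_step
  if (!is.finite(lo) || !is.finite(hi) || lo > hi)
    return(rec("noncontact"))
  V <- seq(lo, hi, by = v_step)
  sm <- slice_minima(segment, placement, Z, V, basis, roots, refine = refine)
  if (!any(is.finite(sm$min)))
    return(rec("noncontact"))
  dmin <- min(sm$min)
  if (dmin <= contact_tol) return(rec("contact"))
  cand <- which(sm$min <= dmin + 1e-9)
  depth <- segment$apical_dir * (Z[cand] - segment$cej_z)
  rec("measurable", dmin, Z[cand[which.min(depth)]])
}

#' @export
print.measurement_record <- function(x, ...) {
  val <- if (x$outcome == "measurable") sprintf("%.3f mm", x$distance)
         else x$outcome
  cat(sprintf("<measurement_record> %s %s %s @%g deg: %s\n",
              x$jaw, x$site, x$side, x$angle, val))
  invisible(x)
}

#' @export
as.data.frame.measurement_record <- function(x, ...) {
  data.frame(subject_id = x$subject_id, jaw = x$jaw, site = x$site,
             side = x$side, angle = x$angle, outcome = x$outcome,
             distance = x$distance, argmin_z = x$argmin_z,
             stringsAsFactors = FALSE)
}
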