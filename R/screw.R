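#' Tapered miniscrew geometry
#'
#' A solid of revolution: the cross-section at axial position
#' `s in [0, length]` (0 = neck, `length` = tip) is a disc of radius
#' `radius_profile(s)`, linear from `neck_diameter/2` down to
#' `tip_diameter/2` by default. The default dimensions are the 1.5 mm x 6 mm
#' tapered body used throughout the analysis; `tip_diameter = neck_diameter`
#' gives a cylinder. Thread geometry is not modeled: the "threaded portion"
#' is the entire shank.
#'
#' @param length shank length, mm
#' @param neck_diameter diameter at the neck (maximum), mm
#' @param tip_diameter diameter at the tip, mm (must not exceed the neck)
#' @return object of class `screw_geometry`
#' @examples
#' screw_radius(build_screw(), 0) # 0.75 mm at the neck
#' screw_radius(build_screw(), 3) # 0.525 mm halfway
#' @export
build_screw <- function(length = 6, neck_diameter = 1.5, tip_diameter = 0.6) {
  if (length <= 0 || neck_diameter <= 0 || tip_diameter <= 0)
    stop("screw dimensions must be positive")
  if (tip_diameter > neck_diameter)
    stop("tip diameter must not exceed neck diameter")
  structure(list(length = length, r_neck = neck_diameter / 2,
                 r_tip = tip_diameter / 2,
                 k = (tip_diameter - neck_diameter) / (2 * length)),
            class = "screw_geometry")
}

#' Screw radius at an axial position
#' @param screw a [build_screw()] object
#' @param s axial position from the neck, mm
#' @return radius, mm
#' @export
screw_radius <- function(screw, s) screw$r_neck + screw$k * s

## mesiodistal midpoint between the facing root surfaces at height z;
## taken at the buccolingual offset where the gap is smallest
gap_midpoint <- function(segment, z) {
  best <- NULL
  for (ra in segment$anterior$roots) for (rp in segment$posterior$roots) {
    sa <- root_section(ra, z)
    sp <- root_section(rp, z)
    if (is.null(sa) || is.null(sp)) next
    xlo <- max(sa$cx - sa$bx, sp$cx - sp$bx)
    xhi <- min(sa$cx + sa$bx, sp$cx + sp$bx)
    if (xlo > xhi) next
    ant <- function(x) sa$cy - sa$ay * sqrt(pmax(1 - ((x - sa$cx) / sa$bx)^2, 0))
    pos <- function(x) sp$cy + sp$ay * sqrt(pmax(1 - ((x - sp$cx) / sp$bx)^2, 0))
    opt <- stats::optimize(function(x) ant(x) - pos(x), c(xlo, xhi))
    if (is.null(best) || opt$objective < best$width)
      best <- list(width = opt$objective, x = opt$minimum,
                   y_mid = (ant(opt$minimum) + pos(opt$minimum)) / 2)
  }
  if (is.null(best)) stop("no interradicular gap at this height")
  best
}

#' Initial (0 degree) miniscrew placement
#'
#' Places the screw per protocol: insertion point on the buccal cortical
#' sheet, 4 mm apical to the (mean) CEJ of the two adjacent teeth, at the
#' mesiodistal midpoint between the facing roots; long axis horizontal
#' (parallel to the transverse occlusal plane), pointing lingually; head in
#' contact with the cortical surface; all of the shank in bone.
#'
#' @param segment a [make_segment()] object, standardized frame
#' @param screw a [build_screw()] object
#' @param cej_offset insertion depth apical to the CEJ, mm (default 4)
#' @return object of class `screw_placement` with fields `insertion_point`,
#'   `axis` (head -> tip), `angle`, `neck_point`, `apex_point`, `screw`
#' @export
initial_placement <- function(segment, screw = build_screw(), cej_offset = 4) {
  cej <- (segment$anterior$cej_level + segment$posterior$cej_level) / 2
  z0 <- cej + segment$apical_dir * cej_offset
  mid <- gap_midpoint(segment, z0)
  ip <- c(sheet_x(segment, z0), mid$y_mid, z0)
  axis <- c(-1, 0, 0)
  pl <- structure(list(insertion_point = ip, axis = axis, angle = 0,
                       neck_point = ip,
                       apex_point = ip + screw$length * axis,
                       screw = screw, cej_offset = cej_offset),
                  class = "screw_placement")
  chk <- check_in_bone(pl, segment)
  if (!chk$pass)
    stop("initial placement fails the in-bone check: ", chk$reason)
  pl
}

#' Angulate a placement vertically
#'
#' Rotates the screw axis about the mesiodistal axis through the insertion
#' point so the tip points apically (up in the maxilla, down in the
#' mandible) at `angle` degrees to the transverse occlusal plane, keeping
#' the mesiodistal position of the axis unchanged, then re-seats the neck
#' along the new axis so the head stays on the cortical sheet.
#'
#' @param placement a [initial_placement()] result
#' @param angle insertion angle in degrees (0 leaves the placement unchanged)
#' @param segment the segment the placement belongs to
#' @return a new `screw_placement`
#' @export
angulate <- function(placement, angle, segment) {
  if (angle == 0) return(placement)
  if (angle < 0 || angle >= 90) stop("angle must lie in [0, 90) degrees")
  a <- angle * pi / 180
  axis <- c(-cos(a), 0, segment$apical_dir * sin(a))
  ip <- placement$insertion_point
  ## re-seat: neck = point on the new axis lying on the cortical sheet
  ## x(t) = ip_x + t*axis_x must equal sheet_x(z(t)), linear in t
  slope <- segment$bone$ridge_slope
  denom <- axis[1] - slope * segment$apical_dir * axis[3]
  num <- sheet_x(segment, ip[3]) - ip[1]
  t0 <- if (abs(denom) < 1e-12) 0 else num / denom
  neck <- ip + t0 * axis
  pl <- placement
  pl$axis <- axis
  pl$angle <- angle
  pl$neck_point <- neck
  pl$apex_point <- neck + placement$screw$length * axis
  chk <- check_in_bone(pl, segment)
  if (!chk$pass)
    stop("angulated placement fails the in-bone check: ", chk$reason)
  pl
}

#' Place a screw at a given insertion angle
#'
#' Convenience wrapper: [initial_placement()] followed by [angulate()].
#'
#' @inheritParams initial_placement
#' @param angle insertion angle, degrees
#' @return a `screw_placement`
#' @export
place_screw <- function(segment, angle = 0, screw = build_screw(),
                        cej_offset = 4) {
  angulate(initial_placement(segment, screw, cej_offset), angle, segment)
}

## orthonormal radial basis perpendicular to the screw axis.
## e1 = +y is valid because the axis never has a mesiodistal component.
screw_basis <- function(axis) {
  if (abs(axis[2]) > 1e-9)
    stop("screw axis must have no mesiodistal component")
  e1 <- c(0, 1, 0)
  e2 <- unitize(crossprod3(axis, e1))
  list(e1 = e1, e2 = e2)
}

#' Verify that all threaded portions lie in bone
#'
#' Samples the screw's lateral surface and apex rim and checks every sample
#' against the modeled bone: not buccal to the cortical sheet (apart from
#' the geometrically unavoidable entry wedge where the tilted shank meets
#' the surface at the head), not beyond the lingual limit, and within the
#' vertical bone stock (alveolar crest to apical extent).
#'
#' @param placement a `screw_placement`
#' @param segment the segment it is placed in
#' @param n_s,n_theta sampling resolution along and around the shank
#' @param tol geometric tolerance, mm
#' @return list with `pass` (logical), and on failure `reason` and the first
#'   violating sample `point`
#' @export
check_in_bone <- function(placement, segment, n_s = 49, n_theta = 48,
                          tol = 1e-6) {
  sc <- placement$screw
  ax <- placement$axis
  eb <- screw_basis(ax)
  ss <- seq(0, sc$length, length.out = n_s)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  S <- rep(ss, each = n_theta)
  TH <- rep(th, times = n_s)
  r <- screw_radius(sc, S)
  P <- matrix(placement$neck_point, length(S), 3, byrow = TRUE) +
    outer(S, ax) + r * (outer(cos(TH), eb$e1) + outer(sin(TH), eb$e2))
  depth <- segment$apical_dir * (P[, 3] - segment$cej_z)
  sinA <- abs(ax[3]); cosA <- abs(ax[1])
  wedge <- pmax(0, r * sinA - S * cosA)
  buccal <- P[, 1] - sheet_x(segment, P[, 3]) - wedge
  fail <- function(i, why) list(pass = FALSE, reason = why, point = P[i, ])
  i <- which(buccal > tol)
  if (length(i)) return(fail(i[1], "shank emerges buccal to the cortical sheet"))
  i <- which(P[, 1] < segment$bone$lingual_x - tol)
  if (length(i)) return(fail(i[1], "apex exits the lingual cortex"))
  i <- which(depth < segment$bone$crest_depth - tol)
  if (length(i)) return(fail(i[1], "shank exits occlusally above the alveolar crest"))
  i <- which(depth > segment$bone$apical_extent + tol)
  if (length(i)) return(fail(i[1], "apex exits the apical bone stock"))
  list(pass = TRUE, reason = NA_character_, point = NULL)
}

#' @export
print.screw_placement <- function(x, ...) {
  cat(sprintf("<screw_placement> angle %g deg; neck (%.2f, %.2f, %.2f); apex (%.2f, %.2f, %.2f)\n",
              x$angle, x$neck_point[1], x$neck_point[2], x$neck_point[3],
              x$apex_point[1], x$apex_point[2], x$apex_point[3]))
  invisible(x)
}
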