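#' Parametric root surface
#'
#' A single root modeled as a tapered elliptical cone with an optional
#' quadratic mesiodistal bow. In the standardized frame the root axis is
#' vertical (cervical to apical); the cross-section at normalized depth
#' `t = depth/length` is an axis-aligned ellipse with semi-axes
#' `semi * (1 - taper * t)` whose mesiodistal center is displaced by
#' `bow * 4 * t * (1 - t)` (peaking at mid-root). Coordinates are mm:
#' x buccolingual (buccal positive), y mesiodistal (mesial positive),
#' z vertical.
#'
#' @param cej_center 3-vector, center of the root section at the
#'   cementoenamel junction (CEJ)
#' @param axis unit direction cervical -> apical; must be vertical
#'   (`c(0, 0, 1)` maxilla, `c(0, 0, -1)` mandible)
#' @param length root length, mm (> 0)
#' @param semi_axis_md mesiodistal semi-axis at the CEJ, mm (> 0)
#' @param semi_axis_bl buccolingual semi-axis at the CEJ, mm (> 0)
#' @param taper fractional radius reduction per unit normalized depth,
#'   in `[0, 1)`
#' @param bow signed peak mesiodistal displacement of the centerline, mm
#'   (positive displaces mesially, toward +y)
#' @return object of class `root_surface`
#' @examples
#' r <- make_root(c(0, 5, 0), c(0, 0, 1), length = 12,
#'                semi_axis_md = 3, semi_axis_bl = 4, taper = 0.5)
#' root_radius(r, depth = 12) # semi-axes halved at the apex
#' @export
make_root <- function(cej_center, axis = c(0, 0, 1), length, semi_axis_md,
                      semi_axis_bl, taper = 0, bow = 0) {
  stopifnot(base::length(cej_center) == 3, base::length(axis) == 3)
  if (!is.finite(length) || length <= 0) stop("root length must be > 0")
  if (semi_axis_md <= 0 || semi_axis_bl <= 0) stop("root semi-axes must be > 0")
  if (taper < 0 || taper >= 1) stop("taper must lie in [0, 1)")
  axis <- unitize(axis)
  if (abs(axis[1]) > 1e-9 || abs(axis[2]) > 1e-9)
    stop("root axis must be vertical in the standardized frame")
  structure(list(cej_center = as.numeric(cej_center), axis = axis,
                 length = length, semi_axis_md = semi_axis_md,
                 semi_axis_bl = semi_axis_bl, taper = taper, bow = bow),
            class = "root_surface")
}

#' Root semi-axes at a given depth
#'
#' Linear taper: `semi(depth) = semi(0) * (1 - taper * depth/length)`.
#'
#' @param root a [make_root()] object
#' @param depth distance from the CEJ along the root axis, mm
#' @return list with `md` and `bl` semi-axes (mm)
#' @export
root_radius <- function(root, depth) {
  f <- 1 - root$taper * depth / root$length
  list(md = root$semi_axis_md * f, bl = root$semi_axis_bl * f)
}

## Cross-section of a root at absolute height z.
## Returns NULL when z is outside the CEJ-apex span, else the axis-aligned
## ellipse: center (cx, cy), semi-axes (bx buccolingual, ay mesiodistal).
root_section <- function(root, z) {
  d <- root$axis[3] * (z - root$cej_center[3])
  if (d < -1e-9 || d > root$length + 1e-9) return(NULL)
  d <- min(max(d, 0), root$length)
  t <- d / root$length
  r <- root_radius(root, d)
  list(cx = root$cej_center[1],
       cy = root$cej_center[2] + root$bow * 4 * t * (1 - t),
       bx = r$bl, ay = r$md, depth = d)
}

#' Sample points on a root surface
#'
#' Parametric sampling of the closed lateral tube, used by mesh export and
#' by voxel-accuracy checks.
#'
#' @param root a [make_root()] object
#' @param n_depth,n_theta grid resolution along depth and around the section
#' @return numeric matrix (n_depth * n_theta) x 3
#' @export
root_surface_points <- function(root, n_depth = 40, n_theta = 60) {
  dd <- seq(0, root$length, length.out = n_depth)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  out <- matrix(NA_real_, n_depth * n_theta, 3)
  k <- 1
  for (d in dd) {
    z <- root$cej_center[3] + root$axis[3] * d
    s <- root_section(root, z)
    out[k:(k + n_theta - 1), ] <- cbind(s$cx + s$bx * cos(th),
                                        s$cy + s$ay * sin(th), z)
    k <- k + n_theta
  }
  out
}
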