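#' Build the standardized occlusal coordinate frame from landmarks
#'
#' Orients a scene the way the measurement protocol does: the occlusal plane
#' defines the horizontal, and the line through the mesiobuccal cusps of the
#' two maxillary first molars defines the transverse axis. The returned
#' frame has `ez` = occlusal-plane normal, `ex` = unit inter-cusp direction
#' (right to left) projected into the plane, `ey = ez x ex`, and origin at
#' the inter-cusp midpoint.
#'
#' The sign of `ez` is fixed by the ordering of `occlusal_points`: the first
#' three must run counterclockwise when viewed from the apical (superior)
#' side, so the recovered frame is equivariant under rigid motions.
#'
#' @param occlusal_points numeric matrix (>= 3 x 3) of non-collinear
#'   landmarks on the occlusal plane
#' @param mb_cusp_left,mb_cusp_right mesiobuccal cusp of the left/right
#'   maxillary first molar
#' @return object of class `occlusal_frame` with fields `origin`, `ex`,
#'   `ey`, `ez`
#' @export
build_occlusal_frame <- function(occlusal_points, mb_cusp_left, mb_cusp_right) {
  pts <- as.matrix(occlusal_points)
  if (nrow(pts) < 3 || ncol(pts) != 3)
    stop("occlusal_points must be a (>= 3) x 3 matrix")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("occlusal landmarks are collinear; cannot define a plane")
  ez <- sv$v[, 3]
  orient <- crossprod3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
  if (sum(orient^2) < 1e-18)
    stop("first three occlusal landmarks are collinear")
  if (sum(ez * orient) < 0) ez <- -ez
  d <- as.numeric(mb_cusp_left - mb_cusp_right)
  if (sqrt(sum(d^2)) < 1e-9) stop("molar cusp landmarks coincide")
  ex <- d - sum(d * ez) * ez
  if (sqrt(sum(ex^2)) < 1e-9)
    stop("inter-cusp line is perpendicular to the occlusal plane")
  ex <- unitize(ex)
  ey <- crossprod3(ez, ex)
  structure(list(origin = as.numeric(mb_cusp_left + mb_cusp_right) / 2,
                 ex = ex, ey = ey, ez = unitize(ez)),
            class = "occlusal_frame")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation/translation of a frame as a 4x4 homogeneous matrix
#'
#' The matrix maps standardized-frame coordinates to world coordinates;
#' suitable for JSON export.
#'
#' @param frame an [build_occlusal_frame()] object
#' @return 4x4 numeric matrix
#' @export
frame_matrix <- function(frame) {
  m <- diag(4)
  m[1:3, 1:3] <- cbind(frame$ex, frame$ey, frame$ez)
  m[1:3, 4] <- frame$origin
  m
}

#' Transform geometry into a standardized frame
#'
#' Applies the rigid world-to-frame transform `p' = R^T (p - origin)` (no
#' scaling; distances and angles are preserved). Methods exist for point
#' matrices/vectors and for posed segments (see [pose_segment()]), the
#' latter rebuilding a parametric `segment_model`.
#'
#' @param x geometry (n x 3 matrix, length-3 vector, or `posed_segment`)
#' @param frame an `occlusal_frame`
#' @param inverse if `TRUE`, map frame coordinates back to world coordinates
#' @return transformed geometry of the same shape/class
#' @export
to_frame <- function(x, frame, inverse = FALSE) UseMethod("to_frame")

#' @export
to_frame.default <- function(x, frame, inverse = FALSE) {
  R <- cbind(frame$ex, frame$ey, frame$ez)
  vec <- is.null(dim(x))
  p <- if (vec) matrix(x, 1, 3) else as.matrix(x)
  out <- if (inverse) sweep(p %*% t(R), 2, frame$origin, `+`)
         else sweep(p, 2, frame$origin) %*% R
  if (vec) as.numeric(out) else out
}

#' @export
to_frame.posed_segment <- function(x, frame, inverse = FALSE) {
  if (inverse) stop("inverse transform of a posed segment is not supported")
  R <- cbind(frame$ex, frame$ey, frame$ez)
  tp <- function(p) as.numeric(to_frame(p, frame))
  td <- function(d) as.numeric(d %*% R)
  seg <- x$segment
  for (side in c("anterior", "posterior")) {
    seg[[side]]$roots <- lapply(seq_along(seg[[side]]$roots), function(i) {
      r <- seg[[side]]$roots[[i]]
      cej <- tp(x$points[[side]]$cej[i, ])
      ax <- td(x$points[[side]]$axis[i, ])
      if (abs(ax[1]) > 1e-6 || abs(ax[2]) > 1e-6)
        stop("recovered root axis is not vertical; frame recovery failed")
      ax <- c(0, 0, sign(ax[3]))
      make_root(cej, ax, r$length, r$semi_axis_md, r$semi_axis_bl,
                r$taper, r$bow)
    })
    seg[[side]]$buccal_cusp <- tp(x$points[[side]]$cusp)
    seg[[side]]$cej_level <- tp(x$points[[side]]$cej[1, ])[3]
  }
  seg$ref_cusps <- to_frame(x$points$ref_cusps, frame)
  rownames(seg$ref_cusps) <- rownames(x$points$ref_cusps)
  seg$cej_z <- (seg$anterior$cej_level + seg$posterior$cej_level) / 2
  class(seg) <- "segment_model"
  seg
}

#' Pose a segment in world coordinates
#'
#' Applies a rigid motion `p -> R p + t` to all defining points of a
#' standardized segment, returning a `posed_segment` whose parametric form
#' can be recovered with [to_frame()] once the occlusal frame has been
#' rebuilt from landmarks. Used by the pose-invariance tests.
#'
#' @param segment a [make_segment()] object
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 translation
#' @return object of class `posed_segment`
#' @export
pose_segment <- function(segment, rotation = diag(3), translation = c(0, 0, 0)) {
  tp <- function(p) as.numeric(rotation %*% p + translation)
  pts <- list()
  for (side in c("anterior", "posterior")) {
    cej <- t(vapply(segment[[side]]$roots, function(r) tp(r$cej_center),
                    numeric(3)))
    ax <- t(vapply(segment[[side]]$roots,
                   function(r) as.numeric(rotation %*% r$axis), numeric(3)))
    pts[[side]] <- list(cej = cej, axis = ax,
                        cusp = tp(segment[[side]]$buccal_cusp))
  }
  pts$ref_cusps <- t(apply(segment$ref_cusps, 1, tp))
  structure(list(segment = segment, points = pts,
                 rotation = rotation, translation = translation),
            class = "posed_segment")
}

#' Posterior reference line of a segment
#'
#' The line through the buccal cusps of the first and second molars on the
#' measured side, oriented mesial to distal. All distance measurements are
#' taken parallel to this line (the molar distalization direction).
#'
#' @param segment a [make_segment()] object
#' @return list with `point` (on the line) and unit `direction`
#'   (mesial -> distal), class `reference_line`
#' @export
posterior_reference_line <- function(segment) {
  a <- segment$ref_cusps[1, ]
  b <- segment$ref_cusps[2, ]
  d <- b - a
  if (sqrt(sum(d^2)) < 1e-9) stop("molar cusp landmarks coincide")
  structure(list(point = as.numeric(a), direction = unitize(d)),
            class = "reference_line")
}
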