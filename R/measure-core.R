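## Internal geometry engine for the slice-based directional measurement.
##
## All in-slice work is done along the family of lines
##   p(lambda) = O2 + v * vhat + lambda * u,    u = in-plane projection of
## the posterior reference line (mesial -> distal), vhat its in-plane
## perpendicular (the buccolingual corridor offset). Both the screw solid
## (a frustum: plane sections are conic regions clipped to the axial slab
## 0 <= s <= L) and a root section (an ellipse) intersect such a line in a
## lambda-interval obtained from a quadratic; gaps, overlaps and contacts
## all reduce to interval arithmetic on a (slice z) x (offset v) grid.

## vectorized root section parameters at heights Z
root_section_vec <- function(root, Z) {
  d <- root$axis[3] * (Z - root$cej_center[3])
  valid <- d >= -1e-9 & d <= root$length + 1e-9
  d <- pmin(pmax(d, 0), root$length)
  t <- d / root$length
  f <- 1 - root$taper * t
  list(valid = valid,
       cx = rep(root$cej_center[1], length(Z)),
       cy = root$cej_center[2] + root$bow * 4 * t * (1 - t),
       bx = root$semi_axis_bl * f,
       ay = root$semi_axis_md * f)
}

## expand a v specification (vector or nz x nv matrix) to a matrix
as_vmat <- function(V, nz) {
  if (is.matrix(V)) V else matrix(V, nz, length(V), byrow = TRUE)
}

## lambda-intervals of the screw solid on the (Z x V) grid
screw_lambda <- function(placement, Z, V, O2, u2, vh2) {
  sc <- placement$screw
  ax <- placement$axis
  n <- placement$neck_point
  nz <- length(Z)
  Vm <- as_vmat(V, nz)
  dx0 <- O2[1] + Vm * vh2[1] - n[1]
  dy0 <- O2[2] + Vm * vh2[2] - n[2]
  dz <- Z - n[3]                       # length nz, recycles down columns
  s1 <- ax[1] * u2[1] + ax[2] * u2[2]
  s0 <- ax[1] * dx0 + ax[2] * dy0 + ax[3] * dz
  kk <- 1 + sc$k^2
  A <- 1 - s1^2 * kk
  if (A <= 1e-9)
    stop("measurement direction is too closely aligned with the screw axis")
  B <- 2 * (dx0 * u2[1] + dy0 * u2[2]) - 2 * kk * s0 * s1 -
       2 * sc$r_neck * sc$k * s1
  C <- dx0^2 + dy0^2 + dz^2 - kk * s0^2 - 2 * sc$r_neck * sc$k * s0 -
       sc$r_neck^2
  qi <- quad_interval(A, B, C)
  ## axial slab 0 <= s0 + s1*lambda <= L
  if (abs(s1) > 1e-12) {
    b1 <- -s0 / s1
    b2 <- (sc$length - s0) / s1
    slab_lo <- pmin(b1, b2)
    slab_hi <- pmax(b1, b2)
  } else {
    inside <- s0 >= 0 & s0 <= sc$length
    slab_lo <- ifelse(inside, -Inf, NA_real_)
    slab_hi <- ifelse(inside, Inf, NA_real_)
  }
  int_intersect(qi$lo, qi$hi, slab_lo, slab_hi)
}

## lambda-intervals of a root's elliptical section on the (Z x V) grid
root_lambda <- function(root, Z, V, O2, u2, vh2) {
  nz <- length(Z)
  Vm <- as_vmat(V, nz)
  rs <- root_section_vec(root, Z)
  X0 <- O2[1] + Vm * vh2[1] - rs$cx
  Y0 <- O2[2] + Vm * vh2[2] - rs$cy
  bx2 <- rs$bx^2
  ay2 <- rs$ay^2
  A <- u2[1]^2 / bx2 + u2[2]^2 / ay2
  B <- 2 * (X0 * u2[1] / bx2 + Y0 * u2[2] / ay2)
  C <- X0^2 / bx2 + Y0^2 / ay2 - 1
  qi <- quad_interval(A, B, C)
  qi$lo[!rs$valid] <- NA_real_
  qi$hi[!rs$valid] <- NA_real_
  qi
}

## in-plane measurement basis from the posterior reference line
measurement_basis <- function(segment, placement) {
  rl <- posterior_reference_line(segment)
  u2 <- rl$direction[1:2]
  nu <- sqrt(sum(u2^2))
  if (nu < 1e-9)
    stop("posterior reference line is vertical; no in-plane measurement direction")
  u2 <- u2 / nu
  list(u2 = u2, vh2 = c(-u2[2], u2[1]),
       O2 = placement$neck_point[1:2])
}

## directional clearance grid between the screw and a set of roots.
## side = "anterior": clearance = screw_lo - root_hi (root mesial of screw)
## side = "posterior": clearance = root_lo - screw_hi
clearance_grid <- function(segment, placement, Z, V, basis, roots,
                           side = "anterior") {
  sl <- screw_lambda(placement, Z, V, basis$O2, basis$u2, basis$vh2)
  nz <- length(Z)
  nv <- if (is.matrix(V)) ncol(V) else length(V)
  gap <- matrix(NA_real_, nz, nv)
  root_any <- matrix(FALSE, nz, nv)
  for (r in roots) {
    rl <- root_lambda(r, Z, V, basis$O2, basis$u2, basis$vh2)
    has <- !is.na(rl$lo)
    root_any <- root_any | has
    g <- if (side == "anterior") sl$lo - rl$hi else rl$lo - sl$hi
    upd <- has & !is.na(sl$lo) & (is.na(gap) | g < gap)
    gap[upd] <- g[upd]
  }
  list(gap = gap, screw_any = !is.na(sl$lo), root_any = root_any,
       both = !is.na(gap))
}

## fast row-wise minima/argmin over a matrix with NAs (NA = empty cell)
row_mins <- function(M) {
  M[is.na(M)] <- Inf
  idx <- max.col(-M, ties.method = "first")
  list(min = M[cbind(seq_len(nrow(M)), idx)], idx = idx)
}

## per-slice refinement: the directional gap is convex in the offset v
## (lower boundary of a convex section minus upper boundary of a convex
## section), so a golden-section search bracketed one grid step around the
## coarse argmin converges to the slice minimum. Offsets outside the
## overlap window evaluate to +Inf, which golden section tolerates; this
## also resolves the square-root-shaped minima at corridor edges that a
## fixed local grid cannot.
refine_slice_minima <- function(segment, placement, Z, V, basis, roots,
                                slice_min, side = "anterior", iters = 24) {
  rows <- which(is.finite(slice_min$min))
  if (!length(rows)) return(slice_min$min)
  step <- V[2] - V[1]
  Zr <- Z[rows]
  best <- slice_min$min[rows]
  a <- V[slice_min$idx[rows]] - step
  b <- V[slice_min$idx[rows]] + step
  evalg <- function(vv) {
    cg <- clearance_grid(segment, placement, Zr, matrix(vv, ncol = 1),
                         basis, roots, side)
    g <- cg$gap[, 1]
    g[is.na(g)] <- Inf
    g
  }
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  cg0 <- clearance_grid(segment, placement, Zr, cbind(x1, x2), basis, roots,
                        side)
  f1 <- cg0$gap[, 1]; f1[is.na(f1)] <- Inf
  f2 <- cg0$gap[, 2]; f2[is.na(f2)] <- Inf
  best <- pmin(best, f1, f2)
  for (it in seq_len(iters)) {
    left <- f1 <= f2
    b[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
    x1[left] <- b[left] - phi * (b[left] - a[left])
    a[!left] <- x1[!left]; x1[!left] <- x2[!left]; f1[!left] <- f2[!left]
    x2[!left] <- a[!left] + phi * (b[!left] - a[!left])
    fnew <- evalg(ifelse(left, x1, x2))
    f1[left] <- fnew[left]
    f2[!left] <- fnew[!left]
    best <- pmin(best, fnew)
  }
  out <- slice_min$min
  out[rows] <- best
  out
}

## per-slice minimum clearance with optional refinement
slice_minima <- function(segment, placement, Z, V, basis, roots,
                         side = "anterior", refine = TRUE) {
  cg <- clearance_grid(segment, placement, Z, V, basis, roots, side)
  rm <- row_mins(cg$gap)
  res <- list(min = rm$min, idx = rm$idx, gap = cg$gap,
              screw_any = cg$screw_any, root_any = cg$root_any)
  if (refine && length(V) > 1 && any(is.finite(rm$min)))
    res$min <- refine_slice_minima(segment, placement, Z, V, basis, roots,
                                   res, side)
  res
}

## conservative v-ranges used to build the offset grid
root_v_range <- function(roots, Z, basis) {
  lo <- Inf; hi <- -Inf
  for (r in roots) {
    rs <- root_section_vec(r, Z)
    if (!any(rs$valid)) next
    cv <- (rs$cx - basis$O2[1]) * basis$vh2[1] +
          (rs$cy - basis$O2[2]) * basis$vh2[2]
    ext <- sqrt((rs$bx * basis$vh2[1])^2 + (rs$ay * basis$vh2[2])^2)
    lo <- min(lo, min((cv - ext)[rs$valid]))
    hi <- max(hi, max((cv + ext)[rs$valid]))
  }
  c(lo, hi)
}

screw_v_range <- function(placement, basis) {
  vn <- sum((placement$neck_point[1:2] - basis$O2) * basis$vh2)
  va <- sum((placement$apex_point[1:2] - basis$O2) * basis$vh2)
  c(min(vn, va) - placement$screw$r_neck,
    max(vn, va) + placement$screw$r_neck)
}

## slice grid between apex and neck (0.1 mm rule), closed at both ends
slice_grid <- function(placement, thickness) {
  z1 <- min(placement$neck_point[3], placement$apex_point[3])
  z2 <- max(placement$neck_point[3], placement$apex_point[3])
  if (z2 - z1 < 1e-12) return(z1)
  zs <- seq(z1, z2, by = thickness)
  if (z2 - zs[length(zs)] > 1e-9) zs <- c(zs, z2)
  zs
}
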