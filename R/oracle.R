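## Independent verification oracle for the slice-based measurement: instead
## of interval algebra on an offset grid, sample points on the boundary of
## the screw's cross-section in every slice (solving the lateral-surface
## height equation per angular sample, plus the cap chords) and cast a ray
## from each sample toward the anterior root parallel to the reference
## line. The reported minimum is a pure minimum over nested sample sets, so
## it converges to the measured value from above as n_samples grows and
## never increases when n_samples is doubled.

## nested angular stream: low-discrepancy half + seeded uniform half
theta_stream <- function(n, seed) {
  m1 <- ceiling(n / 2)
  m2 <- n - m1
  u <- if (m2 > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    stats::runif(m2)
  } else numeric(0)
  2 * pi * c(vdc(m1), u)
}

## boundary points of the screw cross-section at height z
screw_section_boundary <- function(placement, z, theta, n_grid = 64) {
  sc <- placement$screw
  ax <- placement$axis
  nk <- placement$neck_point
  eb <- screw_basis(ax)
  pts <- NULL
  if (abs(ax[3]) < 1e-6) {
    ## horizontal axis: the slice boundary is parametrized by the axial
    ## position, y = yn +/- sqrt(r(s)^2 - dz^2); sample s with the same
    ## nested stream mapped onto [0, L]
    sg <- sc$length * (theta / (2 * pi))
    dz <- z - nk[3]
    h2 <- screw_radius(sc, sg)^2 - dz^2
    sg <- sg[h2 > 0]
    if (length(sg)) {
      h <- sqrt(screw_radius(sc, sg)^2 - dz^2)
      base <- matrix(nk, length(sg), 3, byrow = TRUE) + outer(sg, ax)
      up <- base; up[, 2] <- up[, 2] + h
      dn <- base; dn[, 2] <- dn[, 2] - h
      up[, 3] <- z; dn[, 3] <- z
      pts <- rbind(up, dn)
    }
  } else {
    ## lateral surface: z(s,theta) = zn + s*az + r(s)*sin(theta)*e2z
    w <- sin(theta) * eb$e2[3]
    den <- ax[3] + sc$k * w
    num <- z - nk[3] - sc$r_neck * w
    ok <- abs(den) > 1e-9
    s <- num[ok] / den[ok]
    th <- theta[ok]
    keep <- s >= 0 & s <= sc$length
    s <- s[keep]; th <- th[keep]
    if (length(s)) {
      r <- screw_radius(sc, s)
      pts <- matrix(nk, length(s), 3, byrow = TRUE) + outer(s, ax) +
        r * (outer(cos(th), eb$e1) + outer(sin(th), eb$e2))
    }
  }
  ## cap chords at s = 0 and s = L
  for (cap in list(list(c = nk, r = sc$r_neck),
                   list(c = placement$apex_point, r = sc$r_tip))) {
    if (abs(eb$e2[3]) > 1e-9) {
      beta <- (z - cap$c[3]) / eb$e2[3]
      if (abs(beta) <= cap$r) {
        amax <- sqrt(cap$r^2 - beta^2)
        ## include the chord endpoints: they lie on the cap rim, where the
        ## mesial extremum of apex-region slices is attained
        alpha <- amax * c(-1, 1, 2 * vdc(max(8, length(theta) %/% 8)) - 1)
        p <- matrix(cap$c, length(alpha), 3, byrow = TRUE) +
          outer(alpha, eb$e1) + outer(rep(beta, length(alpha)), eb$e2)
        pts <- rbind(pts, p)
      }
    } else if (abs(z - cap$c[3]) < 1e-9) {
      phi <- seq(0, 2 * pi, length.out = max(16, length(theta) %/% 4))
      p <- matrix(cap$c, length(phi), 3, byrow = TRUE) +
        cap$r * (outer(cos(phi), eb$e1) + outer(sin(phi), eb$e2))
      pts <- rbind(pts, p)
    }
  }
  pts
}

## ray from a 2D point (lp, vp) toward -u: nearest root boundary and
## containment, for one elliptical section
ray_to_ellipse <- function(lp, vp, sec, O2, u2, vh2) {
  x0 <- O2[1] + vp * vh2[1] - sec$cx
  y0 <- O2[2] + vp * vh2[2] - sec$cy
  A <- u2[1]^2 / sec$bx^2 + u2[2]^2 / sec$ay^2
  B <- 2 * (x0 * u2[1] / sec$bx^2 + y0 * u2[2] / sec$ay^2)
  C <- x0^2 / sec$bx^2 + y0^2 / sec$ay^2 - 1
  disc <- B^2 - 4 * A * C
  lo <- (-B - sqrt(pmax(disc, 0))) / (2 * A)
  hi <- (-B + sqrt(pmax(disc, 0))) / (2 * A)
  miss <- disc < 0
  list(lo = ifelse(miss, NA_real_, lo), hi = ifelse(miss, NA_real_, hi))
}

#' Brute-force verification of the slice-based measurement
#'
#' Independent oracle: in each 0.1-mm slice, points on the boundary of the
#' screw cross-section (dense random plus low-discrepancy angular sampling,
#' nested so that doubling `n_samples` never loses a sample) are generated
#' from the surface parametrization, and from each point a ray is cast
#' parallel to the reference line toward the anterior root. The minimum hit
#' distance over all samples and slices converges to the measured
#' miniscrew-root distance from above. Contact is additionally screened by
#' testing a 3D surface sample of the screw for containment in either
#' tooth's root.
#'
#' @inheritParams measure_placement
#' @param n_samples angular samples per slice
#' @param seed integer seed for the random half of the sampling
#' @return object of class `measurement_record` (side/ids copied from the
#'   segment), with attribute `"n_samples"`
#' @export
brute_force_distance <- function(segment, placement, n_samples = 800,
                                 seed = 1, slice_thickness = 0.1,
                                 subject_id = NA_character_) {
  basis <- measurement_basis(segment, placement)
  u2 <- basis$u2; vh2 <- basis$vh2; O2 <- basis$O2
  rec <- function(outcome, distance = NA_real_, argmin_z = NA_real_) {
    structure(list(subject_id = subject_id, jaw = segment$jaw,
                   site = segment$site, side = segment$side,
                   angle = placement$angle, outcome = outcome,
                   distance = distance, argmin_z = argmin_z,
                   n_samples = n_samples),
              class = "measurement_record")
  }
  ## 3D containment screen for contact (both teeth, full solid extent)
  sc <- placement$screw
  eb <- screw_basis(placement$axis)
  sg <- seq(0, sc$length, length.out = 80)
  tg <- seq(0, 2 * pi, length.out = 81)[-1]
  S <- rep(sg, each = length(tg)); TH <- rep(tg, times = length(sg))
  P3 <- matrix(placement$neck_point, length(S), 3, byrow = TRUE) +
    outer(S, placement$axis) + screw_radius(sc, S) *
      (outer(cos(TH), eb$e1) + outer(sin(TH), eb$e2))
  for (tooth in list(segment$anterior, segment$posterior)) {
    for (r in tooth$roots) {
      rs <- root_section_vec(r, P3[, 3])
      inside <- rs$valid &
        ((P3[, 1] - rs$cx) / rs$bx)^2 + ((P3[, 2] - rs$cy) / rs$ay)^2 <= 1
      if (any(inside)) return(rec("contact"))
    }
  }
  Z <- slice_grid(placement, slice_thickness)
  best <- Inf
  best_z <- NA_real_
  any_hit <- FALSE
  for (i in seq_along(Z)) {
    z <- Z[i]
    theta <- theta_stream(n_samples, child_seed(seed, i))
    pts <- screw_section_boundary(placement, z, theta)
    if (is.null(pts) || !nrow(pts)) next
    lp <- (pts[, 1] - O2[1]) * u2[1] + (pts[, 2] - O2[2]) * u2[2]
    vp <- (pts[, 1] - O2[1]) * vh2[1] + (pts[, 2] - O2[2]) * vh2[2]
    for (r in segment$anterior$roots) {
      sec <- {
        rs <- root_section_vec(r, z)
        if (!rs$valid) next
        list(cx = rs$cx, cy = rs$cy, bx = rs$bx, ay = rs$ay)
      }
      hit <- ray_to_ellipse(lp, vp, sec, O2, u2, vh2)
      contained <- !is.na(hit$lo) & hit$lo <= lp & lp <= hit$hi
      if (any(contained)) return(rec("contact"))
      g <- lp - hit$hi
      g <- g[!is.na(g) & g >= 0]
      if (length(g)) {
        any_hit <- TRUE
        if (min(g) < best) { best <- min(g); best_z <- z }
      }
    }
  }
  if (!any_hit) return(rec("noncontact"))
  if (best <= 0) return(rec("contact"))
  rec("measurable", best, best_z)
}
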