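#' Default generator parameters for an interradicular site
#'
#' Plausible literature-scale dimensions (mm) for the two posterior teeth
#' bounding each insertion site, the mesiodistal gap between the facing root
#' surfaces at the CEJ, and the buccal ridge. They are generator
#' configuration, not measured claims, and every entry can be overridden.
#' The shipped values realize the qualitative width-versus-depth profiles
#' the analysis assumes: monotone apical widening at Mx 5-6, Mn 5-6 and
#' Mn 6-7 (tapered, diverging roots), and a mid-root constriction at Mx 6-7
#' produced by opposing root bows.
#'
#' @param jaw `"Mx"` or `"Mn"`
#' @param site `"5-6"` or `"6-7"`
#' @return named list of site parameters
#' @export
site_defaults <- function(jaw = c("Mx", "Mn"), site = c("5-6", "6-7")) {
  jaw <- match.arg(jaw)
  site <- match.arg(site)
  premolar <- list(label = "5", length = 13.5, semi_md = 2.2, semi_bl = 3.8,
                   taper = 0.42, bow = 0)
  molar6 <- list(label = "6", length = 12.5, semi_md = 3.3, semi_bl = 4.6,
                 taper = 0.35, bow = 0)
  molar7 <- list(label = "7", length = 12.0, semi_md = 3.2, semi_bl = 4.4,
                 taper = 0.33, bow = 0)
  p <- list(
    crest_depth = 1.5, apical_margin = 4, lingual_margin = 6,
    ridge_slope = 0, crown_height = 6.5, molar_md_halfwidth = 5,
    cej_z = 0
  )
  if (site == "5-6") {
    p$anterior <- premolar
    p$posterior <- molar6
    p$gap_cej <- if (jaw == "Mx") 2.2 else 2.3
    p$ridge_offset <- if (jaw == "Mx") 1.3 else 1.1
  } else {
    p$anterior <- molar6
    p$posterior <- molar7
    if (jaw == "Mx") {
      ## near-cylindrical facing surfaces with strong opposing bows toward
      ## the gap -> corridor narrowest near mid-root, not at the apex
      p$anterior$taper <- 0.03
      p$posterior$taper <- 0.03
      p$anterior$bow <- -1.2
      p$posterior$bow <- 1.2
      p$gap_cej <- 4.4
      p$ridge_offset <- 1.1
    } else {
      p$anterior$taper <- 0.30
      p$posterior$taper <- 0.28
      p$gap_cej <- 2.4
      p$ridge_offset <- 1.1
    }
  }
  p
}

merge_params <- function(base, overrides) {
  if (is.null(overrides)) return(base)
  stopifnot(is.list(overrides))
  utils::modifyList(base, overrides)
}

make_tooth <- function(spec, center_y, cej_z, apical_dir, crown_height) {
  root <- make_root(cej_center = c(0, center_y, cej_z),
                    axis = c(0, 0, apical_dir),
                    length = spec$length, semi_axis_md = spec$semi_md,
                    semi_axis_bl = spec$semi_bl, taper = spec$taper,
                    bow = spec$bow)
  cusp <- c(spec$semi_bl * 0.9, center_y, cej_z - apical_dir * crown_height)
  structure(list(label = spec$label, roots = list(root), buccal_cusp = cusp,
                 cej_level = cej_z), class = "tooth_model")
}

#' Build a parametric interradicular segment
#'
#' Assembles the 3D scene for one insertion site in the standardized frame
#' (x buccolingual, buccal positive; y mesiodistal, mesial positive;
#' z vertical, apical direction +z in the maxilla and -z in the mandible):
#' the two adjacent teeth with facing root surfaces, the buccal cortical
#' sheet, and the molar buccal-cusp landmarks that define the posterior
#' reference line. Facial type scales the mandibular (not maxillary) buccal
#' ridge offset. Optional seeded jitter perturbs the geometry slightly; the
#' cohort generator uses it for left/right asymmetry.
#'
#' @param jaw `"Mx"` or `"Mn"`
#' @param site `"5-6"` or `"6-7"`
#' @param facial_type group name or a [facial_type_params()] list
#' @param side `"left"` or `"right"` (label only; geometry is side-symmetric
#'   up to jitter)
#' @param overrides named list merged over [site_defaults()]
#' @param jitter_sd scale (mm) of the seeded geometric jitter; 0 disables
#' @param seed integer seed for the jitter draws
#' @return object of class `segment_model`
#' @export
make_segment <- function(jaw = c("Mx", "Mn"), site = c("5-6", "6-7"),
                         facial_type = "normodivergent", side = "right",
                         overrides = list(), jitter_sd = 0, seed = NULL) {
  jaw <- match.arg(jaw)
  site <- match.arg(site)
  if (is.character(facial_type)) facial_type <- facial_type_params(facial_type)
  p <- merge_params(site_defaults(jaw, site), overrides)
  scale <- if (jaw == "Mn") facial_type$mandibular_ridge_scale
           else facial_type$maxillary_ridge_scale
  p$ridge_offset <- p$ridge_offset * scale
  if (jaw == "Mn")
    p$gap_cej <- p$gap_cej + (facial_type$mandibular_gap_delta %||% 0)

  jit <- function(n, s) rep(0, n)
  if (jitter_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    jit <- function(n, s) stats::rnorm(n, 0, s * jitter_sd)
  }
  p$gap_cej <- p$gap_cej + jit(1, 1)
  p$ridge_offset <- max(p$ridge_offset + jit(1, 0.6), 0.2)
  tj <- jit(2, 0.10)
  p$anterior$taper <- min(max(p$anterior$taper * (1 + tj[1]), 0), 0.95)
  p$posterior$taper <- min(max(p$posterior$taper * (1 + tj[2]), 0), 0.95)
  bj <- jit(2, 0.35)
  p$anterior$bow <- p$anterior$bow + bj[1]
  p$posterior$bow <- p$posterior$bow + bj[2]
  cusp_jit <- matrix(jit(6, 0.5), 2, 3)

  if (p$gap_cej <= 0)
    stop("overrides produce root interpenetration at the CEJ (gap <= 0)")

  apical_dir <- if (jaw == "Mx") 1 else -1
  ya <- p$gap_cej / 2 + p$anterior$semi_md
  yp <- -(p$gap_cej / 2 + p$posterior$semi_md)
  anterior <- make_tooth(p$anterior, ya, p$cej_z, apical_dir, p$crown_height)
  posterior <- make_tooth(p$posterior, yp, p$cej_z, apical_dir, p$crown_height)

  x_buccal <- max(p$anterior$semi_bl, p$posterior$semi_bl) + p$ridge_offset
  bone <- list(x_buccal = x_buccal, ridge_slope = p$ridge_slope,
               lingual_x = -(max(p$anterior$semi_bl, p$posterior$semi_bl) +
                             p$lingual_margin),
               crest_depth = p$crest_depth,
               apical_extent = max(p$anterior$length, p$posterior$length) +
                               p$apical_margin)

  ## buccal cusps of the first and second molars (mesial landmark first);
  ## at 5-6 sites the second molar is not part of the scene and its cusp is
  ## synthesized one molar width distally.
  if (site == "6-7") {
    ref <- rbind(anterior$buccal_cusp, posterior$buccal_cusp)
  } else {
    c6 <- posterior$buccal_cusp
    ref <- rbind(c6, c6 + c(0, -2 * p$molar_md_halfwidth, 0))
  }
  ref <- ref + cusp_jit
  rownames(ref) <- c("first_molar", "second_molar")

  seg <- structure(list(jaw = jaw, site = site, side = side,
                        apical_dir = apical_dir,
                        anterior = anterior, posterior = posterior,
                        bone = bone, ref_cusps = ref,
                        cej_z = p$cej_z, params = p,
                        facial_type = facial_type$group),
                   class = "segment_model")

  ## sanity: facing surfaces must not cross anywhere on the common span.
  ## the roots share their buccolingual center, so the narrowest gap at any
  ## depth is on the x = 0 plane: a vectorized closed form suffices
  zz <- p$cej_z + apical_dir *
    seq(0, min(p$anterior$length, p$posterior$length), length.out = 40)
  sa <- root_section_vec(anterior$roots[[1]], zz)
  sp <- root_section_vec(posterior$roots[[1]], zz)
  w <- (sa$cy - sa$ay) - (sp$cy + sp$ay)
  if (any(w <= 0))
    warning("root surfaces interpenetrate below the CEJ for these parameters")
  seg
}

## buccal cortical sheet: x offset as a function of height z
sheet_x <- function(segment, z) {
  depth <- segment$apical_dir * (z - segment$cej_z)
  segment$bone$x_buccal + segment$bone$ridge_slope * (depth - 4)
}

#' Interradicular width at a given depth
#'
#' Minimum mesiodistal gap, in the horizontal plane at `depth` mm apical to
#' the CEJ, between the distal surface of the anterior tooth's root and the
#' mesial surface of the posterior tooth's root (minimized over the
#' buccolingual offsets covered by both sections).
#'
#' @param segment a [make_segment()] object
#' @param depth mm apical to the CEJ; must lie within both roots
#' @return width in mm (can be negative if surfaces interpenetrate)
#' @export
interradicular_width <- function(segment, depth) {
  lmin <- min(vapply(c(segment$anterior$roots, segment$posterior$roots),
                     function(r) r$length, numeric(1)))
  if (depth < 0 || depth > lmin)
    stop("depth must lie in [0, ", lmin, "] mm")
  z <- segment$cej_z + segment$apical_dir * depth
  best <- Inf
  for (ra in segment$anterior$roots) for (rp in segment$posterior$roots) {
    sa <- root_section(ra, z)
    sp <- root_section(rp, z)
    if (is.null(sa) || is.null(sp)) next
    xlo <- max(sa$cx - sa$bx, sp$cx - sp$bx)
    xhi <- min(sa$cx + sa$bx, sp$cx + sp$bx)
    if (xlo > xhi) next
    gap <- function(x) {
      (sa$cy - sa$ay * sqrt(pmax(1 - ((x - sa$cx) / sa$bx)^2, 0))) -
      (sp$cy + sp$ay * sqrt(pmax(1 - ((x - sp$cx) / sp$bx)^2, 0)))
    }
    opt <- stats::optimize(gap, c(xlo, xhi))
    best <- min(best, opt$objective, gap(xlo), gap(xhi))
  }
  if (!is.finite(best)) stop("no common buccolingual support at this depth")
  best
}

#' @export
print.segment_model <- function(x, ...) {
  cat(sprintf("<segment_model> %s %s (%s, %s)\n", x$jaw, x$site, x$side,
              x$facial_type))
  cat(sprintf("  gap at CEJ: %.2f mm; buccal sheet at x = %.2f mm\n",
              x$params$gap_cej, x$bone$x_buccal))
  invisible(x)
}
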