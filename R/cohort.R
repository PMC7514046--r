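#' Default cohort/simulation configuration
#'
#' Central knob set for the whole pipeline. Subject-level anatomical
#' standard deviations (mm, or multiplier SDs) describe between-subject
#' variation; `side_jitter` (mm) is the much smaller left/right asymmetry
#' within a subject. The defaults give cohort cell SDs of roughly
#' 0.1-0.5 mm, growing with insertion angle.
#'
#' @param n_per_group subjects per facial-type group (default 20, i.e. a
#'   60-subject cohort)
#' @param angles insertion angles in degrees
#' @param seed master seed; every random draw in the pipeline derives from it
#' @param ... overrides for any listed element
#' @return named list
#' @export
default_config <- function(n_per_group = 20, angles = c(0, 30, 45, 60),
                           seed = 1, ...) {
  cfg <- list(
    n_per_group = n_per_group,
    angles = angles,
    seed = seed,
    subject_sd = list(gap = 0.22, ridge = 0.25, taper_mult = 0.08,
                      bow = 0.10),
    side_jitter = 0.06,
    screw = list(length = 6, neck_diameter = 1.5, tip_diameter = 0.6),
    cej_offset = 4,
    slice_thickness = 0.1,
    v_step = 0.05,
    refine = TRUE,
    voxel_size = 0.1,
    mode = "analytic",
    segment_overrides = list(),
    ## TRUE removes every facial-type effect from the geometry (labels are
    ## kept): the null world for type-I error simulations
    null_facial_effect = FALSE
  )
  utils::modifyList(cfg, list(...))
}

draw_group_covariates <- function(group) {
  cv <- facial_type_params(group)$covariates
  repeat {
    mp <- stats::rnorm(1, cv$mp_mean, cv$mp_sd)
    fhi <- stats::rnorm(1, cv$fhi_mean, cv$fhi_sd)
    if (classify_facial_type(mp, fhi) == group) return(c(mp = mp, fhi = fhi))
  }
}

#' Simulate a cohort of subjects with bilateral posterior segments
#'
#' Draws, per facial-type group, subject covariates (sex, mandibular plane
#' angle, facial height index; Gaussian at the group means/SDs, redrawn
#' whenever the two classification rules disagree, mirroring the exclusion
#' rule) and per-site anatomical deviations (interradicular gap, ridge
#' offset, root taper multipliers, bows), then builds the 8 segments
#' (2 jaws x 2 sites x 2 sides) per subject with small seeded left/right
#' jitter. Fully deterministic given `(config, seed)`.
#'
#' @param n_per_group subjects per group
#' @param config a [default_config()] list
#' @param seed master seed (overrides `config$seed`)
#' @return object of class `cohort`: list of `subjects`, plus `config`
#' @export
simulate_cohort <- function(n_per_group = 20, config = default_config(),
                            seed = config$seed) {
  stopifnot(n_per_group >= 1)
  sdz <- config$subject_sd
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  subjects <- list()
  sid <- 0L
  for (gi in seq_along(facial_groups())) {
    group <- facial_groups()[gi]
    ftp <- facial_type_params(group)
    if (isTRUE(config$null_facial_effect)) {
      ftp$mandibular_ridge_scale <- 1
      ftp$maxillary_ridge_scale <- 1
      ftp$mandibular_gap_delta <- 0
    }
    cv <- ftp$covariates
    for (i in seq_len(n_per_group)) {
      sid <- sid + 1L
      id <- sprintf("S%03d", sid)
      cov <- draw_group_covariates(group)
      sex <- if (stats::runif(1) < cv$p_male) "M" else "F"
      age <- max(20, stats::rnorm(1, cv$age_mean, cv$age_sd))
      segments <- list()
      for (jaw in c("Mx", "Mn")) for (site in c("5-6", "6-7")) {
        base <- site_defaults(jaw, site)
        ov <- config$segment_overrides[[paste(jaw, site)]] %||% list()
        ov$gap_cej <- (ov$gap_cej %||% base$gap_cej) +
          stats::rnorm(1, 0, sdz$gap)
        ov$ridge_offset <- max((ov$ridge_offset %||% base$ridge_offset) *
          stats::rnorm(1, 1, sdz$ridge / base$ridge_offset), 0.2)
        tm <- stats::rnorm(2, 1, sdz$taper_mult)
        bw <- stats::rnorm(2, 0, sdz$bow)
        ov$anterior <- utils::modifyList(
          ov$anterior %||% list(),
          list(taper = min(max(base$anterior$taper * tm[1], 0), 0.9),
               bow = base$anterior$bow + bw[1]))
        ov$posterior <- utils::modifyList(
          ov$posterior %||% list(),
          list(taper = min(max(base$posterior$taper * tm[2], 0), 0.9),
               bow = base$posterior$bow + bw[2]))
        for (side in c("left", "right")) {
          key <- paste(jaw, site, side, sep = "_")
          segments[[key]] <- make_segment(
            jaw, site, facial_type = ftp, side = side, overrides = ov,
            jitter_sd = config$side_jitter,
            seed = child_seed(seed, gi, i, match(jaw, c("Mx", "Mn")),
                              match(site, c("5-6", "6-7")),
                              match(side, c("left", "right"))))
        }
      }
      subjects[[id]] <- structure(
        list(id = id, facial_type = group, sex = sex, age = age,
             mp_angle = unname(cov["mp"]), fhi = unname(cov["fhi"]),
             segments = segments),
        class = "subject")
    }
  }
  structure(list(subjects = subjects,
                 config = utils::modifyList(config,
                   list(n_per_group = n_per_group, seed = seed))),
            class = "cohort")
}

#' Subject covariates of a cohort as a data frame
#' @param cohort a [simulate_cohort()] object
#' @return data.frame with one row per subject
#' @export
cohort_covariates <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$id, facial_type = s$facial_type, sex = s$sex,
               age = s$age, mp_angle = s$mp_angle, fhi = s$fhi,
               stringsAsFactors = FALSE)
  }))
}

#' Measure every placement of a cohort
#'
#' Runs the full placement + measurement protocol for each subject, jaw,
#' site, side and insertion angle, producing long-format records.
#'
#' @param cohort a [simulate_cohort()] object
#' @param config configuration (defaults to the cohort's own)
#' @return data.frame with one row per placement: identifiers, covariates,
#'   `outcome`, `distance`, `argmin_z`
#' @export
measure_cohort <- function(cohort, config = cohort$config) {
  screw <- build_screw(config$screw$length, config$screw$neck_diameter,
                       config$screw$tip_diameter)
  out <- vector("list", length(cohort$subjects) * 32L)
  k <- 0L
  for (s in cohort$subjects) {
    for (seg in s$segments) {
      p0 <- initial_placement(seg, screw, cej_offset = config$cej_offset)
      for (a in config$angles) {
        pl <- angulate(p0, a, seg)
        m <- if (identical(config$mode, "voxel")) {
          vol <- voxelize_segment(seg, config$voxel_size)
          vol <- rasterize_screw(vol, pl)
          voxel_measure(vol, pl, segment = seg, subject_id = s$id)
        } else {
          measure_placement(seg, pl, config$slice_thickness, config$v_step,
                            refine = config$refine %||% TRUE,
                            subject_id = s$id)
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          subject_id = s$id, facial_type = s$facial_type, sex = s$sex,
          mp_angle = s$mp_angle, fhi = s$fhi, jaw = seg$jaw, site = seg$site,
          side = seg$side, angle = a, outcome = m$outcome,
          distance = m$distance, argmin_z = m$argmin_z,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}
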