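#' Classify vertical facial type from cephalometric measurements
#'
#' Applies the two-rule classification used to stratify subjects into
#' vertical facial types. The mandibular plane angle (S-N/Go-Me) rule reads:
#' below 27 degrees hypodivergent, 27-37 normodivergent, above 37
#' hyperdivergent. The facial height index (S-Go/N-Me) rule reads: below 61%
#' hyperdivergent, 61-69% normodivergent, above 69% hypodivergent. A subject
#' is assigned a facial type only when the two rules agree; discordant
#' combinations return `"EXCLUDED"`. Values exactly on a boundary are
#' normodivergent under that rule.
#'
#' @param mp_angle mandibular plane angle S-N/Go-Me, degrees
#' @param fhi facial height index S-Go/N-Me, percent
#' @return character vector over `"hyperdivergent"`, `"normodivergent"`,
#'   `"hypodivergent"`, `"EXCLUDED"`
#' @examples
#' classify_facial_type(23.9, 75.3) # hypodivergent
#' classify_facial_type(42.5, 58.7) # hyperdivergent
#' classify_facial_type(25, 58)     # EXCLUDED (rules disagree)
#' @export
classify_facial_type <- function(mp_angle, fhi) {
  stopifnot(is.numeric(mp_angle), is.numeric(fhi), length(mp_angle) == length(fhi))
  if (any(!is.finite(mp_angle)) || any(!is.finite(fhi)))
    stop("mp_angle and fhi must be finite")
  by_angle <- ifelse(mp_angle < 27, "hypodivergent",
              ifelse(mp_angle > 37, "hyperdivergent", "normodivergent"))
  by_ratio <- ifelse(fhi < 61, "hyperdivergent",
              ifelse(fhi > 69, "hypodivergent", "normodivergent"))
  ifelse(by_angle == by_ratio, by_angle, "EXCLUDED")
}

#' Facial-type generator parameters
#'
#' Per-group parameters consumed by the anatomy generator: a multiplier on
#' the mandibular buccal ridge offset (hypodivergent > normodivergent >
#' hyperdivergent, the mandible-only ridge-thickness effect), an equal
#' maxillary multiplier, a small mandibular interradicular-gap offset
#' (mandibular bone morphology differs globally across facial types, not
#' only in cortex thickness; a perpendicular screw crosses the whole
#' corridor, so ridge thickness alone transmits almost no facial effect at
#' 0 degrees), and the covariate distributions (means/SDs of the mandibular
#' plane angle and facial height index, and the male fraction) from which
#' subjects are drawn.
#'
#' @param group one of `"hyperdivergent"`, `"normodivergent"`, `"hypodivergent"`
#' @return list with `group`, `mandibular_ridge_scale`,
#'   `maxillary_ridge_scale`, `mandibular_gap_delta` (mm) and `covariates`
#'   (means/SDs for `mp_angle`, `fhi`, plus `p_male`, age)
#' @export
facial_type_params <- function(group = c("hyperdivergent", "normodivergent",
                                         "hypodivergent")) {
  group <- match.arg(group)
  cov <- switch(group,
    hyperdivergent = list(mp_mean = 42.5, mp_sd = 3.7, fhi_mean = 58.7,
                          fhi_sd = 1.9, p_male = 4 / 20,
                          age_mean = 25.3, age_sd = 6.1),
    normodivergent = list(mp_mean = 33.6, mp_sd = 2.3, fhi_mean = 66.8,
                          fhi_sd = 1.8, p_male = 7 / 20,
                          age_mean = 25.2, age_sd = 7.2),
    hypodivergent  = list(mp_mean = 23.9, mp_sd = 3.7, fhi_mean = 75.3,
                          fhi_sd = 3.5, p_male = 12 / 20,
                          age_mean = 28.2, age_sd = 8.9))
  scale <- switch(group,
    hyperdivergent = 0.80,
    normodivergent = 1.00,
    hypodivergent  = 1.20)
  gap_delta <- switch(group,
    hyperdivergent = -0.18,
    normodivergent = 0,
    hypodivergent  = 0.18)
  list(group = group,
       mandibular_ridge_scale = scale,
       maxillary_ridge_scale = 1.0,
       mandibular_gap_delta = gap_delta,
       covariates = cov)
}

facial_groups <- function() c("hyperdivergent", "normodivergent", "hypodivergent")
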