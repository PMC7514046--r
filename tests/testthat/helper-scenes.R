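# Shared fixtures: all geometry is built in code at test time.

# segment with two vertical cylinder roots (taper 0, bow 0) and a flat
# vertical sheet; exact closed forms exist for every measurement
cylinder_segment <- function(gap = 3, r_md = 2, r_bl = 3, jaw = "Mn",
                             ridge_offset = 1.2, len = 13) {
  ov <- list(
    gap_cej = gap, ridge_offset = ridge_offset,
    anterior = list(label = "5", length = len, semi_md = r_md,
                    semi_bl = r_bl, taper = 0, bow = 0),
    posterior = list(label = "6", length = len, semi_md = r_md,
                     semi_bl = r_bl, taper = 0, bow = 0))
  make_segment(jaw, "5-6", overrides = ov)
}

# minimal hand-built segment: single anterior/posterior roots at given
# centers; reference line along -y
manual_segment <- function(ant, post, apical_dir = 1, x_buccal = 8) {
  tooth <- function(root, label) {
    structure(list(label = label, roots = list(root),
                   buccal_cusp = c(root$semi_axis_bl, root$cej_center[2],
                                   root$cej_center[3] - apical_dir * 6),
                   cej_level = root$cej_center[3]),
              class = "tooth_model")
  }
  ref <- rbind(first_molar = c(4, -2, -6 * apical_dir),
               second_molar = c(4, -12, -6 * apical_dir))
  structure(list(jaw = if (apical_dir > 0) "Mx" else "Mn", site = "5-6",
                 side = "right", apical_dir = apical_dir,
                 anterior = tooth(ant, "5"), posterior = tooth(post, "6"),
                 bone = list(x_buccal = x_buccal, ridge_slope = 0,
                             lingual_x = -20, crest_depth = -20,
                             apical_extent = 40),
                 ref_cusps = ref, cej_z = 0,
                 params = list(gap_cej = NA), facial_type = "normodivergent"),
            class = "segment_model")
}

# screw placement built directly (bypasses protocol constraints)
manual_placement <- function(neck, axis, screw = build_screw(), angle = NA) {
  axis <- axis / sqrt(sum(axis^2))
  structure(list(insertion_point = neck, axis = axis, angle = angle,
                 neck_point = neck, apex_point = neck + screw$length * axis,
                 screw = screw, cej_offset = NA),
            class = "screw_placement")
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# landmark set whose recovered occlusal frame is the identity
identity_landmarks <- function() {
  list(occ = rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
       left = c(25, 0, 0), right = c(-25, 0, 0))
}

# synthetic long-format record table for stats-layer tests
make_records <- function(n_subj = 4, angles = c(0, 30), jaws = "Mn",
                         sites = "5-6", base = 1.2, subj_sd = 0.2,
                         side_sd = 0.05, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subj)) {
    id <- sprintf("S%02d", i)
    for (jaw in jaws) for (site in sites) {
      mu <- base + rnorm(1, 0, subj_sd)
      for (a in angles) {
        for (side in c("left", "right")) {
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = id, facial_type = "normodivergent", sex = "F",
            mp_angle = 33, fhi = 66, jaw = jaw, site = site, side = side,
            angle = a, outcome = "measurable",
            distance = mu + a / 100 + rnorm(1, 0, side_sd),
            argmin_z = NA_real_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
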