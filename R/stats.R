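#' Ordinal categorization of miniscrew-root outcomes
#'
#' Maps each outcome to the 7-level ordinal code: contact = 0; measurable
#' distances binned with inclusive upper edges, (0, 0.5] = 1, (0.5, 1] = 2,
#' (1, 1.5] = 3, (1.5, 2] = 4, > 2 = 5; noncontact = 6.
#'
#' @param x a `measurement_record`, a data frame with `outcome`/`distance`
#'   columns, or a numeric vector of measurable distances (mm)
#' @param ... unused
#' @return integer vector of categories 0-6
#' @examples
#' categorize(1.2)  # 3
#' categorize(0.5)  # 1 (upper edge inclusive)
#' @export
categorize <- function(x, ...) UseMethod("categorize")

#' @export
categorize.numeric <- function(x, ...) {
  if (any(!is.na(x) & x <= 0))
    stop("measurable distances must be positive")
  ## left.open gives (lo, hi] bins, so exact upper edges stay in the
  ## lower category (0.5 -> 1, 1 -> 2, ...)
  unname(1L + findInterval(x, c(0.5, 1, 1.5, 2), left.open = TRUE))
}

#' @export
categorize.measurement_record <- function(x, ...) {
  switch(x$outcome,
         contact = 0L,
         noncontact = 6L,
         measurable = categorize(x$distance),
         stop("unknown outcome: ", x$outcome))
}

#' @export
categorize.data.frame <- function(x, ...) {
  out <- integer(nrow(x))
  out[x$outcome == "contact"] <- 0L
  out[x$outcome == "noncontact"] <- 6L
  m <- x$outcome == "measurable"
  out[m] <- categorize(x$distance[m])
  out
}

#' Average the two sides of a bilateral measurement pair
#'
#' Both measurable: mean distance. Both contact (or both noncontact): that
#' outcome. Discordant measurability: the measurable side's value wins and
#' the record is flagged `discordant`. A contact/noncontact discordance
#' (no measurable side) resolves to contact, flagged.
#'
#' @param left,right `measurement_record`s or single-row data frames with
#'   matching subject/jaw/site/angle
#' @return a single averaged record (list) with a `discordant` field
#' @export
bilateral_average <- function(left, right) {
  g <- function(r, f) if (is.data.frame(r)) r[[f]][1] else r[[f]]
  for (f in c("subject_id", "jaw", "site", "angle")) {
    if (!identical(g(left, f), g(right, f)))
      stop("bilateral pair mismatch on ", f)
  }
  ol <- g(left, "outcome"); or <- g(right, "outcome")
  dl <- g(left, "distance"); dr <- g(right, "distance")
  out <- list(subject_id = g(left, "subject_id"), jaw = g(left, "jaw"),
              site = g(left, "site"), angle = g(left, "angle"),
              discordant = FALSE)
  if (ol == "measurable" && or == "measurable") {
    out$outcome <- "measurable"; out$distance <- (dl + dr) / 2
  } else if (ol == or) {
    out$outcome <- ol; out$distance <- NA_real_
  } else if (ol == "measurable" || or == "measurable") {
    out$outcome <- "measurable"
    out$distance <- if (ol == "measurable") dl else dr
    out$discordant <- TRUE
  } else {
    out$outcome <- "contact"; out$distance <- NA_real_
    out$discordant <- TRUE
  }
  out
}

#' Bilaterally average a long-format record table
#'
#' Pairs left/right rows per subject x jaw x site x angle, applies
#' [bilateral_average()], and attaches the ordinal `category`.
#'
#' @param records data frame from [measure_cohort()]
#' @return data frame with one row per subject x jaw x site x angle
#' @export
average_bilateral <- function(records) {
  key <- interaction(records$subject_id, records$jaw, records$site,
                     records$angle, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(records)), key), function(ix) {
    stopifnot(length(ix) == 2)
    l <- records[ix[records$side[ix] == "left"], ]
    r <- records[ix[records$side[ix] == "right"], ]
    b <- bilateral_average(l, r)
    cbind(data.frame(b[c("subject_id", "jaw", "site", "angle", "outcome",
                         "distance", "discordant")],
                     stringsAsFactors = FALSE),
          l[, c("facial_type", "sex", "mp_angle", "fhi"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$category <- categorize(out)
  out[order(out$subject_id, out$jaw, out$site, out$angle), ]
}

#' Paired left/right comparison of measurable distances
#'
#' Two-sided paired t-test on left minus right differences over pairs where
#' both sides are measurable (the protocol's justification for averaging
#' sides). Differences are first averaged within subject so the test's
#' units are independent; the 16 conditions of one subject share anatomy
#' and would otherwise violate the t-test's independence assumption.
#' Degenerate zero-variance cases are reported as such rather than
#' erroring.
#'
#' @param records long-format record table (with `side`)
#' @return list with `statistic`, `p`, `n_pairs` (subjects contributing),
#'   `mean_diff`, `degenerate`
#' @export
paired_side_test <- function(records) {
  key <- interaction(records$subject_id, records$jaw, records$site,
                     records$angle, drop = TRUE)
  pair_rows <- lapply(split(seq_len(nrow(records)), key), function(ix) {
    l <- records[ix[records$side[ix] == "left"], ]
    r <- records[ix[records$side[ix] == "right"], ]
    if (nrow(l) == 1 && nrow(r) == 1 &&
        l$outcome == "measurable" && r$outcome == "measurable")
      data.frame(subject_id = l$subject_id, d = l$distance - r$distance)
    else NULL
  })
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs) || nrow(pairs) < 2)
    stop("need at least 2 bilateral measurable pairs")
  diffs <- tapply(pairs$d, pairs$subject_id, mean)
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2)
    stop("need bilateral measurable pairs from at least 2 subjects")
  if (stats::sd(diffs) < 1e-12) {
    m <- mean(diffs)
    return(list(statistic = if (abs(m) < 1e-12) 0 else sign(m) * Inf,
                p = if (abs(m) < 1e-12) 1 else 0,
                n_pairs = length(diffs), mean_diff = m, degenerate = TRUE))
  }
  tt <- stats::t.test(diffs)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       n_pairs = length(diffs), mean_diff = mean(diffs), degenerate = FALSE)
}

cell_groups <- function(df, by) {
  f <- lapply(by, function(b) factor(df[[b]]))
  names(f) <- by
  f
}

#' Mean and SD of measurable distances per cell
#'
#' Cell statistics over measurable rows only, by jaw x site x angle x facial
#' type, plus pooled (`facial_type = "Total"`) rows. Cells with no
#' measurable rows are kept with `n = 0` and `NA` statistics.
#'
#' @param avg bilaterally averaged table from [average_bilateral()]
#' @return data.frame with `n`, `mean`, `sd` per cell
#' @export
summarize_measurable <- function(avg) {
  stopifnot(nrow(avg) > 0)
  one <- function(df) {
    grid <- expand.grid(jaw = unique(avg$jaw), site = unique(avg$site),
                        angle = sort(unique(avg$angle)),
                        facial_type = unique(df$facial_type),
                        stringsAsFactors = FALSE)
    stats_df <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      sel <- df$jaw == g$jaw & df$site == g$site & df$angle == g$angle &
             df$facial_type == g$facial_type & df$outcome == "measurable"
      d <- df$distance[sel]
      data.frame(g, n = length(d),
                 mean = if (length(d)) mean(d) else NA_real_,
                 sd = if (length(d) > 1) stats::sd(d) else NA_real_)
    }))
    stats_df
  }
  tot <- avg
  tot$facial_type <- "Total"
  out <- rbind(one(tot), one(avg))
  rownames(out) <- NULL
  out
}

#' Rate of miniscrew-root distances above 2 mm
#'
#' Percentage of rows (all outcomes in the denominator; equivalently
#' category 5 rows) per jaw x site x angle.
#'
#' @param avg bilaterally averaged table
#' @return data.frame with `n`, `n_gt2`, `pct`
#' @export
rate_gt2 <- function(avg) {
  stopifnot(nrow(avg) > 0)
  sp <- split(avg, list(avg$jaw, avg$site, avg$angle), drop = FALSE, sep = "|")
  out <- do.call(rbind, lapply(names(sp), function(k) {
    df <- sp[[k]]
    ks <- strsplit(k, "|", fixed = TRUE)[[1]]
    n5 <- sum(df$category == 5L)
    data.frame(jaw = ks[1], site = ks[2], angle = as.numeric(ks[3]),
               n = nrow(df), n_gt2 = n5,
               pct = if (nrow(df)) 100 * n5 / nrow(df) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out[order(out$jaw, out$site, out$angle), ]
}

#' Rates of non-measurable outcomes per cell
#'
#' Contact and noncontact percentages by jaw x site x angle x facial type;
#' the denominator is the number of subjects in the facial-type group.
#'
#' @param avg bilaterally averaged table
#' @return data.frame with `n`, `pct_contact`, `pct_noncontact`
#' @export
nonmeasurable_rates <- function(avg) {
  stopifnot(nrow(avg) > 0)
  grid <- expand.grid(jaw = unique(avg$jaw), site = unique(avg$site),
                      angle = sort(unique(avg$angle)),
                      facial_type = unique(avg$facial_type),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sel <- avg$jaw == g$jaw & avg$site == g$site & avg$angle == g$angle &
           avg$facial_type == g$facial_type
    n <- sum(sel)
    data.frame(g, n = n,
               pct_contact = if (n) 100 * sum(avg$outcome[sel] == "contact") / n else NA_real_,
               pct_noncontact = if (n) 100 * sum(avg$outcome[sel] == "noncontact") / n else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Ordinal category counts
#'
#' Category frequency table over a (partition of a) cohort; counts always
#' sum to the number of rows.
#'
#' @param avg bilaterally averaged table
#' @return data.frame with `category` (0-6) and `count`
#' @export
category_counts <- function(avg) {
  data.frame(category = 0:6,
             count = vapply(0:6, function(k) sum(avg$category == k),
                            integer(1)))
}
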