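rec_row <- function(outcome, distance = NA_real_, side = "left",
                    subject = "S01", jaw = "Mn", site = "5-6", angle = 0) {
  data.frame(subject_id = subject, facial_type = "normodivergent", sex = "F",
             mp_angle = 33, fhi = 66, jaw = jaw, site = site, side = side,
             angle = angle, outcome = outcome, distance = distance,
             argmin_z = NA_real_, stringsAsFactors = FALSE)
}

test_that("categorization reproduces the 7-level coding", {
  expect_identical(categorize(1.2), 3L)
  expect_identical(categorize(0.8), 2L)
  expect_identical(categorize(0.3), 1L)
  expect_identical(categorize(1.7), 4L)
  expect_identical(categorize(2.4), 5L)
  # inclusive upper edges
  expect_identical(categorize(c(0.5, 1, 1.5, 2)), c(1L, 2L, 3L, 4L))
  expect_identical(categorize(2 + 1e-12), 5L)
  df <- rbind(rec_row("contact"), rec_row("noncontact"),
              rec_row("measurable", 1.2))
  expect_identical(categorize(df), c(0L, 6L, 3L))
  expect_error(categorize(-1), "positive")
})

test_that("categorization is monotone over measurable distances", {
  set.seed(2)
  x <- sort(runif(300, 0.01, 4))
  expect_true(all(diff(categorize(x)) >= 0))
})

test_that("bilateral averaging follows the decision rules", {
  l <- rec_row("measurable", 1.0, "left")
  r <- rec_row("measurable", 1.4, "right")
  b <- bilateral_average(l, r)
  expect_equal(b$distance, 1.2)
  expect_false(b$discordant)
  b2 <- bilateral_average(rec_row("contact"), rec_row("contact", side = "right"))
  expect_equal(b2$outcome, "contact")
  b3 <- bilateral_average(rec_row("measurable", 2.0),
                          rec_row("noncontact", side = "right"))
  expect_equal(b3$outcome, "measurable")
  expect_equal(b3$distance, 2.0)
  expect_true(b3$discordant)
  b4 <- bilateral_average(rec_row("contact"),
                          rec_row("noncontact", side = "right"))
  expect_equal(b4$outcome, "contact")
  expect_true(b4$discordant)
  r_bad <- rec_row("measurable", 1, "right", angle = 30)
  expect_error(bilateral_average(l, r_bad), "mismatch")
})

test_that("paired side test handles identical and degenerate inputs", {
  rec <- make_records(n_subj = 6, seed = 3)
  same <- rec
  same$distance[same$side == "right"] <- same$distance[same$side == "left"]
  out <- paired_side_test(same)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  off <- rec
  off$distance[off$side == "left"] <-
    off$distance[off$side == "right"] + 0.3
  out2 <- paired_side_test(off)
  expect_true(out2$degenerate)
  expect_equal(out2$p, 0)
  expect_error(paired_side_test(rec[rec$side == "left", ]), "pairs")
})

test_that("paired side test holds its nominal size under symmetric jitter", {
  set.seed(31)
  reject <- logical(1000)
  for (i in seq_len(1000)) {
    rec <- make_records(n_subj = 10, angles = c(0, 30), seed = 4000 + i)
    reject[i] <- paired_side_test(rec)$p < 0.05
  }
  rate <- mean(reject)
  mc_se <- sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, 0.05 - 2.5 * mc_se)
  expect_lt(rate, 0.05 + 2.5 * mc_se)
})

test_that("measurable summaries use only measurable rows", {
  rec <- make_records(n_subj = 5, seed = 6)
  rec$distance <- 1.0
  avg <- average_bilateral(rec)
  s <- summarize_measurable(avg)
  tot <- s[s$facial_type == "Total" & s$angle == 0, ]
  expect_equal(tot$mean, 1.0)
  expect_equal(tot$sd, 0)
  expect_equal(tot$n, 5)
  # mixed outcomes: non-measurable rows excluded from mean but kept in n-free
  rec2 <- rec
  rec2$outcome[rec2$subject_id == "S01"] <- "noncontact"
  rec2$distance[rec2$subject_id == "S01"] <- NA
  rec2$distance[rec2$outcome == "measurable"] <- 2.0
  s2 <- summarize_measurable(average_bilateral(rec2))
  tot2 <- s2[s2$facial_type == "Total" & s2$angle == 0, ]
  expect_equal(tot2$n, 4)
  expect_equal(tot2$mean, 2.0)
})

test_that("rate tables compute the printed percentages", {
  rec <- make_records(n_subj = 20, angles = 0, seed = 8)
  rec$distance <- 1.0
  big <- c("S01", "S02", "S03")
  rec$distance[rec$subject_id %in% big] <- 2.5
  avg <- average_bilateral(rec)
  t4 <- rate_gt2(avg)
  expect_equal(t4$pct, 15)          # 3 of 20
  expect_equal(t4$n, 20)
  avg0 <- average_bilateral(make_records(n_subj = 4, seed = 9))
  expect_true(all(rate_gt2(avg0)$pct == 0))
  # non-measurable rates: 11 of 20 noncontact -> 55%
  rec2 <- make_records(n_subj = 20, angles = 0, seed = 10)
  nc <- sprintf("S%02d", 1:11)
  rec2$outcome[rec2$subject_id %in% nc] <- "noncontact"
  rec2$distance[rec2$subject_id %in% nc] <- NA
  t5 <- nonmeasurable_rates(average_bilateral(rec2))
  expect_equal(t5$pct_noncontact, 55)
  expect_equal(t5$pct_contact, 0)
})

test_that("category counts are conserved and tables are order-invariant", {
  rec <- make_records(n_subj = 8, angles = c(0, 30, 45, 60), seed = 12)
  avg <- average_bilateral(rec)
  cc <- category_counts(avg)
  expect_equal(sum(cc$count), nrow(avg))
  perm <- sample(nrow(rec))
  avg2 <- average_bilateral(rec[perm, ])
  expect_equal(summarize_measurable(avg2), summarize_measurable(avg))
  expect_equal(rate_gt2(avg2), rate_gt2(avg))
  # left/right relabeling leaves summaries unchanged
  rec3 <- rec
  rec3$side <- ifelse(rec$side == "left", "right", "left")
  expect_equal(summarize_measurable(average_bilateral(rec3)),
               summarize_measurable(avg))
})

test_that("rounding helper rounds half away from zero", {
  expect_equal(round_half_up(71.65, 1), 71.7)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(2.5, 0), 3)
})
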