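test_that("summarize_times reproduces the worked examples", {
  s <- summarize_times(c(2, 2, 2, 2), n_sown = 4)
  expect_equal(s$cv, 0)
  expect_equal(s$mean, 2)
  expect_equal(s$pct_germination, 100)

  s2 <- summarize_times(c(rep(2, 5), rep(3, 5)), n_sown = 10)
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$cv, stats::sd(c(rep(2, 5), rep(3, 5))) / 2.5)
  expect_equal(s2$cv, 0.21081851067789195)  # sample (n-1) sd convention
  expect_equal(s2$mode, 2)                  # tie broken to the earliest bin
})

test_that("the 1% reporting filter uses the 10-of-1000 boundary", {
  expect_false(summarize_times(rep(3, 9), n_sown = 1000)$reportable)
  expect_true(summarize_times(rep(3, 10), n_sown = 1000)$reportable)
  s0 <- summarize_times(numeric(0), n_sown = 100)
  expect_false(s0$reportable)
  expect_equal(s0$pct_germination, 0)
  expect_true(is.na(s0$cv) && is.na(s0$mean) && is.na(s0$mode))
})

test_that("summarize_times validates inputs", {
  expect_error(summarize_times(c(1, -2), 10), "positive")
  expect_error(summarize_times(1:5, 3), "n_sown")
  expect_error(summarize_times(1:5, 10, bin_width = 0), "bin_width")
})

test_that("CV is scale invariant; mean and mode scale", {
  set.seed(2)
  t0 <- stats::rgamma(200, 2, 0.1) + 1
  a <- summarize_times(t0, 500, bin_width = 1)
  b <- summarize_times(3 * t0, 500, bin_width = 3)
  expect_equal(a$cv, b$cv)
  expect_equal(b$mean, 3 * a$mean)
  expect_equal(b$mode, 3 * a$mode)
  # adding a late tail to a peaked sample strictly increases CV
  peaked <- rep(c(2, 3), 50)
  expect_gt(summarize_times(c(peaked, rep(25, 10)), 200)$cv,
            summarize_times(peaked, 200)$cv)
})

make_table <- function() {
  germination_counts(data.frame(
    line_id = rep(c("A", "A", "B"), each = 3),
    replicate_id = rep(c("r1", "r2", "r1"), each = 3),
    plate_id = rep(c("A_r1", "A_r2", "B_r1"), each = 3),
    day = rep(c(2, 3, 5), 3),
    n_germinated = c(40, 80, 20, 50, 60, 10, 3, 4, 2),
    n_sown = rep(c(150, 150, 150), each = 3)))
}

test_that("count tables are validated", {
  expect_error(germination_counts(data.frame(line_id = 1)), "missing column")
  bad <- data.frame(line_id = "A", replicate_id = "r1", plate_id = "P",
                    day = c(2, 2), n_germinated = c(5, 5), n_sown = 150)
  expect_error(germination_counts(bad), "strictly increasing")
  bad2 <- data.frame(line_id = "A", replicate_id = "r1", plate_id = "P",
                     day = c(1, 2), n_germinated = c(100, 100), n_sown = 150)
  expect_error(germination_counts(bad2), "more seeds germinated than sown")
})

test_that("summarize_counts expands counts and applies the plate filter", {
  per_plate <- summarize_counts(make_table())
  expect_equal(nrow(per_plate), 3)
  b <- per_plate[per_plate$plate_id == "B_r1", ]
  expect_true(b$excluded)        # 9 germinated < 10
  a1 <- per_plate[per_plate$plate_id == "A_r1", ]
  expect_false(a1$excluded)
  # expansion round trip: equals summarize_times on the raw day list
  raw <- rep(c(2, 3, 5), c(40, 80, 20))
  ref <- summarize_times(raw, 150, bin_width = 1)
  expect_equal(a1$cv, ref$cv)
  expect_equal(a1$mean, ref$mean)
  expect_equal(a1$mode, ref$mode)
  expect_equal(a1$pct_germination, ref$pct_germination)
  # single-day plate: cv 0, mode = the day
  one_day <- germination_counts(data.frame(
    line_id = "C", replicate_id = "r1", plate_id = "C_r1", day = 3,
    n_germinated = 150, n_sown = 150))
  s <- summarize_counts(one_day)
  expect_equal(s$cv, 0); expect_equal(s$mode, 3)
  expect_equal(s$pct_germination, 100)
})

test_that("line aggregation is the unweighted mean over included plates", {
  per_plate <- summarize_counts(make_table())
  lines <- suppressMessages(aggregate_line(per_plate))
  expect_equal(nrow(lines), 1)    # line B dropped: its only plate excluded
  a <- per_plate[per_plate$line_id == "A", ]
  expect_equal(lines$cv, mean(a$cv))
  expect_equal(lines$n_plates, 2)
  # permutation symmetry
  lines2 <- suppressMessages(aggregate_line(per_plate[c(3, 1, 2), ]))
  expect_equal(lines2$cv, lines$cv)
  # three plates with CVs .1 .2 .3 average to .2
  fake <- data.frame(line_id = "L", cv = c(0.1, 0.2, 0.3), mean = 3, mode = 3,
                     pct_germination = 90, excluded = FALSE)
  expect_equal(aggregate_line(fake)$cv, 0.2)
})

test_that("trait correlation is Spearman and matches rank-then-Pearson", {
  d <- data.frame(cv = c(0.1, 0.3, 0.2, 0.5), mode = c(2, 4, 3, 6))
  expect_equal(trait_correlation(d, "cv", "cv")$rho, 1)
  d$neg <- -d$cv
  expect_equal(trait_correlation(d, "cv", "neg")$rho, -1)
  set.seed(3)
  d2 <- data.frame(cv = stats::runif(20), mode = stats::runif(20))
  expect_equal(trait_correlation(d2, "cv", "mode")$rho,
               stats::cor(rank(d2$cv), rank(d2$mode)))
  expect_error(trait_correlation(d2[1:2, ], "cv", "mode"), "at least 3")
  expect_error(trait_correlation(d2, "cv", "nope"), "unknown trait")
})
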