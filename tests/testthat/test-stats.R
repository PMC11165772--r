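# cohort statistics

# samples with exact mean m and SD s
exact_sample <- function(n, m, s, seed) {
  set.seed(seed)
  as.numeric(scale(rnorm(n))) * s + m
}

test_that("normality screen passes normal data and is location invariant", {
  set.seed(1)
  x <- rnorm(100)
  r <- check_normality(x)
  expect_gt(r$p, 0.05)
  expect_true(r$normal)
  r2 <- check_normality(x + 100)
  expect_equal(r2$D, r$D, tolerance = 1e-12)   # studentized statistic
  expect_error(check_normality(rep(1, 10)), "zero variance")
  expect_error(check_normality(rnorm(4)), "n >= 5")
})

test_that("normality screen rejects exponential data almost always", {
  # The uncorrected KS default (estimated parameters) is conservative; its
  # measured power against exponential(1) at n = 100 is ~0.9. The
  # Monte-Carlo Lilliefors correction restores calibration and rejects
  # essentially always.
  set.seed(2)
  rejected <- replicate(200, check_normality(rexp(100))$p <= 0.05)
  expect_gte(mean(rejected), 0.85)
  set.seed(3)
  rej_lillie <- replicate(40, check_normality(rexp(100), lilliefors = TRUE,
                                              B = 300)$p <= 0.05)
  expect_gte(mean(rej_lillie), 0.95)
})

test_that("identical groups give t = 0 and p = 1", {
  v <- exact_sample(20, 10, 2, seed = 3)
  tab <- rbind(
    data.frame(subject = paste0("m", 1:20), sex = "male", side = "left",
               fraction = 50, W_mm = v, H_mm = 15, AR = v / 15, length_mm = 40),
    data.frame(subject = paste0("f", 1:20), sex = "female", side = "left",
               fraction = 50, W_mm = v, H_mm = 15, AR = v / 15, length_mm = 40))
  r <- compare_sexes(tab, "W", fractions = 50)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
})

test_that("pooled t matches the closed form on constructed summaries", {
  # means 12.0 vs 10.0, common SD 2.1, n = 42 vs 30 (printed width regime)
  x <- exact_sample(42, 12, 2.1, seed = 4)
  y <- exact_sample(30, 10, 2.1, seed = 5)
  tab <- rbind(
    data.frame(subject = paste0("m", 1:42), sex = "male", side = "left",
               fraction = 50, W_mm = x, H_mm = 15, AR = x / 15, length_mm = 40),
    data.frame(subject = paste0("f", 1:30), sex = "female", side = "left",
               fraction = 50, W_mm = y, H_mm = 15, AR = y / 15, length_mm = 40))
  r <- compare_sexes(tab, "W", fractions = 50)
  t_closed <- (12 - 10) / (2.1 * sqrt(1 / 42 + 1 / 30))
  expect_equal(r$t, t_closed, tolerance = 1e-6)
  expect_equal(r$t, 3.984, tolerance = 1e-3)
  expect_lt(r$p, 0.001)
  expect_true(r$significant)
  # agrees with stats::t.test as an independent implementation
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
})

test_that("degenerate group sizes yield flagged NA, never a silent p", {
  tab <- data.frame(subject = c("a", "b"), sex = c("male", "female"),
                    side = "left", fraction = 50, W_mm = c(1, 2), H_mm = 2,
                    AR = c(0.5, 1), length_mm = 40)
  expect_warning(r <- compare_sexes(tab, "W", fractions = 50), "degenerate")
  expect_true(is.na(r$p))
  expect_false(isTRUE(r$significant))
  expect_error(compare_sexes(tab[tab$sex == "male", ], "W"), "both sexes")
})

test_that("Welch flag switches the degrees of freedom", {
  x <- exact_sample(30, 10, 4, seed = 8)
  y <- exact_sample(10, 9, 1, seed = 9)
  tab <- rbind(
    data.frame(subject = paste0("m", 1:30), sex = "male", side = "left",
               fraction = 50, W_mm = x, H_mm = 15, AR = x / 15, length_mm = 40),
    data.frame(subject = paste0("f", 1:10), sex = "female", side = "left",
               fraction = 50, W_mm = y, H_mm = 15, AR = y / 15, length_mm = 40))
  rp <- compare_sexes(tab, "W", fractions = 50, var_equal = TRUE)
  rw <- compare_sexes(tab, "W", fractions = 50, var_equal = FALSE)
  expect_equal(rp$df, 38)
  expect_lt(rw$df, 38)
  tt <- t.test(x, y)
  expect_equal(rw$p, tt$p.value, tolerance = 1e-12)
})

test_that("anterior/posterior contrast reproduces the step-profile arithmetic", {
  ar_step <- c(0.6, rep(0.600, 4), 0.672, rep(0.744, 4), 0.744)
  tab <- table_from_ar(replicate(12, ar_step, simplify = FALSE))
  ap <- ap_contrast(tab)
  expect_equal(ap$anterior_mean, 0.600)
  expect_equal(ap$posterior_mean, 0.744)
  expect_equal(ap$percent_difference, (1 - 0.600 / 0.744) * 100,
               tolerance = 1e-9)
  expect_equal(ap$percent_difference, 19.4, tolerance = 0.05)
  expect_true(all(ap$pairs$significant))
})

test_that("constant AR profiles give zero contrast and p = 1", {
  tab <- table_from_ar(replicate(10, rep(0.7, 11), simplify = FALSE))
  ap <- ap_contrast(tab)
  expect_equal(ap$percent_difference, 0)
  expect_true(all(ap$pairs$p == 1))
})

test_that("a fixed anterior-posterior offset is significant from n = 5", {
  set.seed(11)
  profs <- lapply(1:10, function(i) {
    base <- 0.7 + rnorm(11, 0, 0.02)
    base[2:5] <- base[2:5] - 0.05      # anterior fractions shifted down
    base
  })
  ap <- ap_contrast(table_from_ar(profs))
  expect_true(all(ap$pairs$p < 0.05))
  expect_gt(ap$percent_difference, 0)
})

test_that("missing fractions are listed in the contrast error", {
  tab <- table_from_ar(replicate(4, rep(0.7, 11), simplify = FALSE))
  expect_error(ap_contrast(tab[tab$fraction != 30, ]), "30")
})

test_that("mirrored cohorts are perfectly symmetric", {
  set.seed(12)
  profs <- lapply(1:8, function(i) 0.6 + rnorm(11, 0, 0.05))
  # same profile for left and right of each subject
  tab <- table_from_ar(rep(profs[1:4], each = 2))
  s <- symmetry_contrast(tab)
  expect_equal(s$mean_diff, 0)
  expect_equal(s$p, 1)
})

test_that("a uniform left inflation is detected", {
  set.seed(13)
  rows <- lapply(1:20, function(i) {
    ar <- 0.6 + rnorm(11, 0, 0.03)
    rbind(data.frame(subject = sprintf("s%02d", i), sex = "male", side = "left",
                     fraction = seq(0, 100, 10), W_mm = (ar + 0.05) * 15,
                     H_mm = 15, AR = ar + 0.05, length_mm = 40),
          data.frame(subject = sprintf("s%02d", i), sex = "male", side = "right",
                     fraction = seq(0, 100, 10), W_mm = ar * 15, H_mm = 15,
                     AR = ar, length_mm = 40))
  })
  s <- symmetry_contrast(do.call(rbind, rows))
  expect_true(s$significant)
  expect_equal(s$mean_diff, 0.05, tolerance = 0.02)
  # single subject errors
  expect_error(symmetry_contrast(rows[[1]]), "two subjects")
})

test_that("post-hoc power has the exact null, printed-regime and limit behaviour", {
  expect_equal(posthoc_power(10, 10, 2, 20, 20, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  # d = 0.952 regime from the printed width summaries
  expect_equal(posthoc_power(12, 10, 2.1, 42, 30), 0.976, tolerance = 0.005)
  p <- sapply(c(5, 10, 20, 40, 80, 160), function(n)
    posthoc_power(11, 10, 2, n, n))
  expect_true(all(diff(p) > 0))
  expect_gt(p[6], 0.99)
  expect_error(posthoc_power(1, 0, 1, 10, 10, alpha = 1.2), "alpha")
  expect_error(posthoc_power(1, 0, 0, 10, 10), "sd_pooled")
  expect_error(posthoc_power(1, 0, 1, 1, 10), "n >= 2")
})

test_that("cohort report covers all parameters in a stable layout", {
  sc <- simulate_cohort(n_subjects_per_sex = c(10, 10), seed = 19)
  rep <- cohort_report(sc)
  expect_s3_class(rep, "stat_report")
  expect_equal(sum(rep$parameter == "length"), 1)
  expect_equal(sum(rep$parameter == "W"), 9)
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  expect_true(all(rep$sd_male >= 0))
  expect_identical(rep$significant, rep$p < 0.05)
})
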