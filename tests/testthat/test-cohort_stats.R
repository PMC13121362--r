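test_that("chi-square is Pearson without continuity correction", {
  homo <- rbind(c(10, 10), c(10, 10))
  r <- chi_square(homo)
  expect_equal(r$statistic_value, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 1)

  # closed form n(ad-bc)^2 / (row/col margins) on random 2x2 tables
  set.seed(314)
  for (i in 1:25) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2, 2)
    expect_equal(chi_square(tab)$statistic_value, oracle_chi2_2x2(tab),
                 tolerance = 1e-12)
  }

  # invariance to row/column permutation
  tab <- rbind(c(12, 3, 7), c(5, 9, 2))
  r0 <- chi_square(tab)
  expect_equal(chi_square(tab[, c(3, 1, 2)])$statistic_value,
               r0$statistic_value)
  expect_equal(chi_square(tab[c(2, 1), ])$statistic_value,
               r0$statistic_value)

  expect_true(chi_square(rbind(c(2, 1), c(1, 3)))$small_expected)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "zero marginal")
  expect_error(chi_square(matrix(5, 1, 2)), "at least 2x2")
})

test_that("Fisher's exact p-values match exhaustive enumeration at fixed margins", {
  r <- fisher_exact(rbind(c(5, 0), c(0, 5)))
  expect_equal(r$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1)))$p_value, 1)

  set.seed(271)
  for (i in 1:40) {
    tab <- matrix(sample(1:8, 4, replace = TRUE), 2, 2)
    if (sum(tab) > 30) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(1, 2, 3)), "2x2")
})

test_that("Mann-Whitney U follows the min(Ux,Uy) convention with exact small-sample p", {
  # x entirely above y: U = 0
  r <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$statistic_value, 0)
  # identical multisets: U = nx*ny/2
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic_value, 9 / 2)

  # exact p equals exhaustive permutation enumeration for nx+ny <= 12
  set.seed(161)
  for (i in 1:30) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- round(rnorm(nx), 1); y <- round(rnorm(ny, 0.5), 1)  # ties possible
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mwu_p(x, y),
                 tolerance = 1e-9)
  }

  # tie-free exact p also agrees with the standard exact test
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }

  # beyond the exact limit the tie-corrected normal approximation is used
  big <- mann_whitney_u(rnorm(20), rnorm(20))
  expect_equal(big$method, "normal_approx")
  expect_gte(big$p_value, 0); expect_lte(big$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis reduces to the Mann-Whitney z^2 for two groups", {
  expect_equal(kruskal_wallis(list(rep(2, 5), rep(2, 4), rep(2, 6)))$statistic_value,
               0)
  set.seed(88)
  x <- rnorm(15); y <- rnorm(18, 0.4)
  H <- kruskal_wallis(list(x, y))$statistic_value
  # z from the (uncorrected) normal form of U; H = z^2 algebraically
  nx <- length(x); ny <- length(y); n <- nx + ny
  ux <- sum(rank(c(x, y))[1:nx]) - nx * (nx + 1) / 2
  z <- (ux - nx * ny / 2) / sqrt(nx * ny * (n + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-9)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Cohen's kappa matches its closed form and simulated independence", {
  expect_equal(cohens_kappa(c("a", "b", "a", "b"), c("a", "b", "a", "b"))$statistic_value,
               1)
  # observed agreement 0.9 with expected 0.5 => kappa = 0.8
  a <- rep(c("x", "y"), each = 10)
  b <- a; b[c(1, 11)] <- c("y", "x")   # 18/20 agree, balanced margins
  r <- cohens_kappa(a, b)
  expect_equal(r$p_observed, 0.9)
  expect_equal(r$p_expected, 0.5)
  expect_equal(r$statistic_value, 0.8)

  # independent raters over 10^4 items: kappa near 0
  set.seed(2024)
  ra <- sample(c("p", "n"), 1e4, replace = TRUE)
  rb <- sample(c("p", "n"), 1e4, replace = TRUE)
  expect_lt(abs(cohens_kappa(ra, rb)$statistic_value), 0.03)

  expect_error(cohens_kappa(c("a", "b"), c("a")), "equal length")
  expect_error(cohens_kappa(c("a", "a"), c("a", "a")), "2 categories")
})

test_that("cohort summaries report median (range) and n (%) per stratum", {
  rec <- make_cohort(glioma_cohort_spec(seed = 5))
  s <- summarize_cohort(rec, "tbr_max", "histology")
  expect_equal(nrow(s), 2)
  oligo <- s[s$stratum == "oligodendroglioma", ]
  sub <- rec$tbr_max[rec$histology == "oligodendroglioma"]
  expect_equal(oligo$median, median(sub))
  expect_equal(oligo$min, min(sub))
  expect_equal(oligo$max, max(sub))

  pos <- summarize_cohort(rec, "pet_positive", "histology")
  o_pos <- pos[pos$stratum == "oligodendroglioma" & pos$level == "TRUE", ]
  expect_equal(o_pos$count, 62)
  expect_equal(o_pos$summary, "62 (91.2%)")

  tt <- summarize_cohort(rec, "ttp_min", "histology")
  expect_equal(sum(tt$n_missing), sum(is.na(rec$ttp_min)))

  expect_error(summarize_cohort(rec, "nope"), "unknown metric")
  expect_error(summarize_cohort(rec, "tbr_max", "nope"), "unknown stratum")
  # direct trivial check
  one <- summarize_cohort(data.frame(patient_id = 1:3, histology = "astrocytoma",
                                     who_grade = 2L, ce_present = FALSE,
                                     pet_positive = TRUE, tbr_max = c(1, 2, 3),
                                     tbr_mean = 1, pet_volume_ml = 1,
                                     curve_class = NA, ttp_min = NA,
                                     dice_flair = NA, dice_ce = NA),
                          "tbr_max")
  expect_equal(one$summary, "2 (1-3)")
})

test_that("record validation enforces the clinical contract", {
  rec <- make_cohort(glioma_cohort_spec(seed = 2))
  expect_silent(validate_patient_records(rec))
  bad <- rec; bad$who_grade[bad$histology == "oligodendroglioma"][1] <- 4L
  expect_error(validate_patient_records(bad), "grade 4")
  bad2 <- rec; bad2$tbr_max[1] <- 0.5
  expect_error(validate_patient_records(bad2), ">= 1")
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rec, f, row.names = FALSE)
  back <- read_patient_records(f)
  expect_equal(back$tbr_max, rec$tbr_max)
  expect_equal(back$curve_class, rec$curve_class)
})
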