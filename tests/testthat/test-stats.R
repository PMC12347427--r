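test_that("Mann-Whitney exact regime matches enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)          # 2 / choose(6, 3)
  expect_match(r$method, "exact")
  ## symmetry of the two-sided p
  r2 <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$p_value, r$p_value)
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "empty_sample")
})

test_that("identical samples give p = 1 in the tie regime", {
  x <- c(2, 4, 6, 8)
  r <- mann_whitney_u(x, x)
  expect_equal(r$statistic, length(x)^2 / 2)
  expect_equal(r$p_value, 1)
  expect_match(r$method, "approximation")
})

test_that("exact p agrees with R's wilcox.test on tie-free small samples", {
  set.seed(17)
  for (i in 1:12) {
    x <- round(runif(sample(3:8, 1), 0, 100), 3)
    y <- round(runif(sample(3:8, 1), 0, 100), 3)
    r <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("approximate p agrees with R's corrected normal approximation", {
  set.seed(23)
  x <- sample(1:20, 30, replace = TRUE)   # ties force the approx regime
  y <- sample(5:25, 24, replace = TRUE)
  r <- mann_whitney_u(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("exact and approximate regimes agree within 0.03 at n = 8, 8", {
  set.seed(41)
  x <- runif(8); y <- runif(8, 0.2, 1.2)
  r_exact <- mann_whitney_u(x, y)
  expect_match(r_exact$method, "exact")
  ref_apx <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_lt(abs(r_exact$p_value - ref_apx$p.value), 0.03)
})

test_that("chi-square matches the closed forms", {
  r0 <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r <- chi_square_independence(matrix(c(20, 10, 10, 20), 2, 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)  # n(ad-bc)^2/(r1 r2 c1 c2)
  expect_equal(r$p_value, pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$df, 1)
})

test_that("chi-square agrees with chisq.test on random 3x3 tables", {
  set.seed(9)
  for (i in 1:10) {
    tab <- matrix(rpois(9, 12) + 1, 3, 3)
    r <- chi_square_independence(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
    ## invariance under row/column permutation
    rp <- chi_square_independence(tab[sample(3), sample(3)])
    expect_equal(rp$statistic, r$statistic, tolerance = 1e-10)
  }
})

test_that("rank-1 tables give zero chi-square and bad tables error", {
  tab <- outer(c(2, 3, 5), c(1, 4, 2))
  expect_lt(chi_square_independence(tab)$statistic, 1e-10)
  expect_error(chi_square_independence(matrix(c(1, -1, 2, 3), 2, 2)),
               class = "invalid_parameter")
  expect_error(chi_square_independence(matrix(c(0, 0, 2, 3), 2, 2)),
               class = "invalid_parameter")
  expect_error(chi_square_independence(matrix(1:3, 1, 3)),
               class = "invalid_parameter")
  r <- chi_square_independence(matrix(c(2, 1, 1, 2), 2, 2))
  expect_true(r$expected_low)
})

test_that("pairwise class comparisons cover the observed class pairs", {
  set.seed(3)
  stim <- c(runif(10, 0, 2), runif(10, 3, 10), runif(10, 13, 25))
  lab <- rep(c("RESORPTION", "NO_ACTIVITY", "APPOSITION"), each = 10)
  pw <- pairwise_class_tests(stim, lab)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_value >= 0 & pw$p_value <= 1))
  expect_true(all(pw$n1 == 10 & pw$n2 == 10))
})
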