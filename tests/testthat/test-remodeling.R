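test_that("stimulus conversion is the documented unit change", {
  expect_equal(mechanical_stimulus(0, 600), 0)
  expect_equal(mechanical_stimulus(0.006, 600), 10)   # MPa -> J/kg
  expect_equal(mechanical_stimulus(0.0012, 600), 2)   # lower-threshold scale
  expect_error(mechanical_stimulus(0.01, 0), class = "domain_error")
  expect_error(mechanical_stimulus(-0.01, 600), class = "domain_error")
})

test_that("the mechanostat classifier follows the lazy-zone rule", {
  t <- threshold_pair(2, 12)
  expect_identical(classify_stimulus(13, t), "APPOSITION")
  expect_identical(classify_stimulus(1, t), "RESORPTION")
  expect_identical(classify_stimulus(12, t), "NO_ACTIVITY")  # boundary
  expect_identical(classify_stimulus(2, t), "NO_ACTIVITY")   # boundary
  expect_error(threshold_pair(5, 5), class = "invalid_parameter")
  expect_error(threshold_pair(-1, 5), class = "invalid_parameter")
})

test_that("classifier equals the three-branch oracle and is monotone", {
  oracle <- function(S, lo, hi) {
    vapply(S, function(s) {
      if (s > hi) "APPOSITION" else if (s < lo) "RESORPTION" else "NO_ACTIVITY"
    }, character(1))
  }
  grid <- seq(0, 30, by = 0.01)
  rank_of <- c(RESORPTION = 1L, NO_ACTIVITY = 2L, APPOSITION = 3L)
  set.seed(2024)
  for (i in 1:100) {
    lo <- runif(1, 0, 10)
    hi <- lo + runif(1, 0.1, 15)
    got <- classify_stimulus(grid, threshold_pair(lo, hi))
    expect_identical(got, oracle(grid, lo, hi))
    expect_true(all(diff(rank_of[got]) >= 0))  # monotone in S
  }
})

test_that("weighted median follows the cumulative-area rule", {
  expect_equal(weighted_median(c(1, 3, 100), c(1, 1, 1)), 3)
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 2)), 3)
  expect_equal(weighted_median(c(5, 5, 5), c(1, 2, 3)), 5)
  ## order invariance
  expect_equal(weighted_median(c(3, 100, 1), c(1, 1, 1)), 3)
})

test_that("zone medians aggregate band elements by zone", {
  stim <- c(1, 3, 100, rep(7, 4), rep(0.5, 7))
  areas <- c(1, 1, 1, rep(2, 4), rep(1, 7))
  zones <- c(1, 1, 1, 2, 2, 2, 2, 3:7, 3, 4)
  med <- zone_median_stimulus(stim, areas, zones)
  expect_equal(unname(med["1"]), 3)
  expect_equal(unname(med["2"]), 7)
  expect_error(zone_median_stimulus(stim[1:3], areas[1:3], c(1, 1, 2)),
               class = "empty_zone")
  ## prediction applies the classifier elementwise
  zs <- predict_zone_remodeling(med, threshold_pair(2, 12))
  expect_identical(zs$predicted[zs$zone_id == 1], "NO_ACTIVITY")
  expect_identical(zs$predicted[zs$zone_id == 3], "RESORPTION")
})

test_that("the lower threshold is the Q1 of resorption-zone stimuli", {
  expect_equal(lower_threshold_from_iqr(c(1, 2, 2, 3, 5, 7, 8)), 2)
  expect_equal(lower_threshold_from_iqr(rep(4.2, 6)), 4.2)
  expect_error(lower_threshold_from_iqr(c(1, 2, 3)), class = "insufficient_data")
  ## agrees with the standard linear-interpolation quantile
  set.seed(31)
  for (i in 1:20) {
    x <- runif(sample(4:40, 1), 0, 10)
    expect_equal(lower_threshold_from_iqr(x),
                 unname(quantile(x, 0.25, type = 7)), tolerance = 1e-12)
  }
})

test_that("classification accuracy counts matches", {
  a <- c("RESORPTION", "NO_ACTIVITY", "APPOSITION")
  expect_equal(classification_accuracy(a, a), 1)
  expect_equal(classification_accuracy(a, rev(a)), 1 / 3)
  pred <- c(a, a, "RESORPTION")                      # 7 entries
  obs <- pred
  obs[c(4, 6)] <- c("APPOSITION", "NO_ACTIVITY")     # two discordant zones
  expect_equal(classification_accuracy(pred, obs), 5 / 7)
  expect_error(classification_accuracy(a, a[1:2]), class = "invalid_parameter")
})

test_that("the brute-force search matches the hand-enumerated example", {
  cal <- calibrate_upper_threshold(c(1, 5, 13),
                                   c("RESORPTION", "NO_ACTIVITY", "APPOSITION"),
                                   t_low = 2, grid = c(5, 20, 0.5))
  expect_equal(cal$accuracy, 1.0)
  expect_equal(cal$plateau, c(5.0, 12.5))
  expect_equal(cal$t_high_star, 8.75)
  ## degenerate case: everything apposition far above the grid
  cal2 <- calibrate_upper_threshold(rep(100, 5), rep("APPOSITION", 5),
                                    t_low = 2, grid = c(3, 25, 0.25))
  expect_equal(cal2$accuracy, 1.0)
  expect_equal(cal2$plateau, c(3, 25))
  expect_error(calibrate_upper_threshold(1, "APPOSITION", t_low = 5,
                                         grid = c(3, 25, 0.25)),
               class = "invalid_parameter")
})

test_that("the grid search equals an independent brute-force oracle", {
  oracle_cal <- function(med, obs, t_low, grid) {
    cand <- seq(grid[1], grid[2], by = grid[3])
    acc <- numeric(length(cand))
    for (k in seq_along(cand)) {
      ok <- 0
      for (i in seq_along(med)) {
        cls <- if (med[i] > cand[k]) "APPOSITION"
               else if (med[i] < t_low) "RESORPTION" else "NO_ACTIVITY"
        if (cls == obs[i]) ok <- ok + 1
      }
      acc[k] <- ok / length(med)
    }
    best <- which(acc == max(acc))
    first <- best[1]
    hi <- first
    while (hi < length(cand) && acc[hi + 1] == max(acc)) hi <- hi + 1
    lo <- first
    while (lo > 1 && acc[lo - 1] == max(acc)) lo <- lo - 1
    list(acc = max(acc), mid = (cand[lo] + cand[hi]) / 2)
  }
  set.seed(11)
  for (i in 1:15) {
    med <- runif(25, 0, 25)
    obs <- sample(stemshield:::remodeling_classes, 25, replace = TRUE)
    cal <- calibrate_upper_threshold(med, obs, t_low = 2, grid = c(3, 25, 0.5))
    orc <- oracle_cal(med, obs, 2, c(3, 25, 0.5))
    expect_equal(cal$accuracy, orc$acc)
    expect_equal(cal$t_high_star, orc$mid)
  }
})

test_that("noiseless forward labels put the generator in the plateau", {
  set.seed(5)
  for (i in 1:10) {
    t_gen <- runif(1, 6, 20)
    med <- runif(60, 0, 30)
    obs <- classify_stimulus(med, threshold_pair(2, t_gen))
    cal <- calibrate_upper_threshold(med, obs, t_low = 2, grid = c(3, 25, 0.1))
    expect_equal(cal$accuracy, 1.0)
    expect_gte(t_gen, cal$plateau[1] - 0.1)
    expect_lte(t_gen, cal$plateau[2] + 0.1)
  }
})

test_that("accuracy is invariant under zone reordering", {
  med <- c(1, 5, 13, 7, 0.4, 19, 3)
  obs <- classify_stimulus(med, threshold_pair(2, 12))
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  c1 <- calibrate_upper_threshold(med, obs, 2, c(3, 25, 0.25))
  c2 <- calibrate_upper_threshold(med[perm], obs[perm], 2, c(3, 25, 0.25))
  expect_equal(c1$accuracy, c2$accuracy)
  expect_equal(c1$t_high_star, c2$t_high_star)
})

test_that("cortical overload measures the exceeding cortical area", {
  tags <- c("CORTICAL", "CORTICAL", "CANCELLOUS", "CORTICAL")
  areas <- c(1, 2, 5, 1)
  expect_equal(cortical_overload(c(1, 2, 50, 3), areas, tags, 12)$overload_fraction, 0)
  ov <- cortical_overload(rep(24, 4), areas, tags, 12)
  expect_equal(ov$overload_fraction, 1)
  expect_equal(ov$max_cortical_stimulus, 24)
  ov2 <- cortical_overload(c(20, 1, 1, 1), areas, tags, 12)
  expect_equal(ov2$overload_fraction, 1 / 4)
})

test_that("stimulus field honours the density mode", {
  sol <- default_solution()
  lit <- stimulus_field(sol$sed, sol$materials, "literal")
  reg <- stimulus_field(sol$sed, sol$materials, "regional")
  bone <- sol$sed$region_tag != "IMPLANT"
  cort <- sol$sed$region_tag == "CORTICAL"
  expect_true(all(is.na(lit[!bone])))
  expect_equal(lit[bone], sol$sed$sed[bone] * 1e6 / 600, tolerance = 1e-12)
  expect_equal(reg[cort], sol$sed$sed[cort] * 1e6 / 1800, tolerance = 1e-12)
  expect_error(stimulus_field(sol$sed, sol$materials, "bogus"),
               class = "invalid_parameter")
})
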