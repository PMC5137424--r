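test_that("top_window_mean matches direct enumeration on known segments", {
  expect_equal(top_window_mean(rep(5, 1000)), 5)
  expect_equal(top_window_mean(0:9, 6), 6.5)
  spike <- c(rep(0, 40), 12, rep(0, 40))
  expect_equal(top_window_mean(spike, 6), 2)
  expect_error(top_window_mean(1:5, 6), "shorter than window")
})

test_that("top_window_mean equals exhaustive enumeration on random segments", {
  withr::with_seed(101, {
    for (i in 1:200) {
      len <- sample(6:400, 1)
      w <- sample(2:6, 1)
      seg <- rpois(len, sample(c(0.5, 2, 10), 1))
      expect_equal(top_window_mean(seg, w), brute_top_window(seg, w))
    }
  })
})

test_that("score normalization is linear in depth and scale-consistent", {
  expect_equal(normalize_score(10, 1e6), 10)
  expect_equal(normalize_score(10, 2e6), 5)
  expect_error(normalize_score(10, 0), "> 0")
  # doubling a track doubles raw score and depth; normalized score fixed
  withr::with_seed(5, vals <- rpois(800, 3))
  tr <- coverage_track(vals)
  tr2 <- coverage_track(vals * 2)
  raw1 <- top_window_mean(track_segment(tr, 100, 700))
  raw2 <- top_window_mean(track_segment(tr2, 100, 700))
  expect_equal(normalize_score(raw1, tr$total_depth),
               normalize_score(raw2, tr2$total_depth))
})

test_that("replicate concordance is the Pearson correlation with guards", {
  x <- c(4, 8, 15, 16, 23, 42, 3, 7, 1, 9)
  expect_equal(replicate_concordance(x, 2 * x), 1)
  expect_equal(replicate_concordance(x, -x), -1)
  expect_error(replicate_concordance(x, rep(1, 10)), "zero variance")
  expect_error(replicate_concordance(x, x[1:5]), "equal length")
})

test_that("Pearson correlation matches the hand-computed textbook formula", {
  x <- c(2, 5, 1, 8, 4, 9, 3, 7, 6, 10)
  y <- c(3, 6, 2, 10, 3, 8, 5, 6, 7, 12)
  n <- 10
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  expect_equal(replicate_concordance(x, y), num / den)
})

test_that("relative difference follows the symmetric formula", {
  expect_equal(relative_difference(1, 1), 0)
  expect_equal(relative_difference(0, 5), -2)
  expect_equal(relative_difference(0.23, 1), 2 * (0.23 - 1) / 1.23)
  expect_equal(round(relative_difference(0.23, 1), 3), -1.252)
  expect_error(relative_difference(0, 0), "undefined")
  expect_error(relative_difference(-1, 2), "non-negative")
})

test_that("classification thresholds partition the RD axis", {
  expect_equal(classify_pre(-0.15), "independent")
  expect_equal(classify_pre(-1.2), "dependent")
  expect_equal(classify_pre(-0.7), "intermediate")
  expect_equal(classify_pre(c(-1.0, -0.5)), rep("intermediate", 2))
  expect_error(classify_pre(NA_real_), "finite")
})

test_that("catalog filtering removes deletion overlaps and weak signals", {
  catalog <- tibble::tibble(chrom = "chr2R",
                            start = seq(0, 10000, by = 1000),
                            end = seq(1000, 11000, by = 1000),
                            name = paste0("p", 1:11))
  scores <- seq(0, 100, by = 10)
  excl <- tibble::tibble(chrom = "chr2R", start = 2500, end = 2600)
  out <- filter_pres(catalog, scores, excl)
  expect_equal(out$filtered_reason[3], "deletion_overlap")  # overlaps 2500
  # dynamic-range rule: threshold 0 + 0.3 * 100 = 30
  expect_equal(out$name[which(out$filtered_reason == "weak_signal")],
               c("p1", "p2"))  # scores 0 and 10 and 20; p3 tagged by overlap
  expect_true(all(is.na(out$filtered_reason[4:11])))
})

test_that("degenerate dynamic range disables the weak-signal rule", {
  catalog <- tibble::tibble(chrom = "c", start = c(0, 1000),
                            end = c(1000, 2000), name = c("a", "b"))
  expect_warning(out <- filter_pres(catalog, c(5, 5)), "range is zero")
  expect_true(all(is.na(out$filtered_reason)))
})

test_that("quantile variant of the weak-signal rule is available", {
  catalog <- tibble::tibble(chrom = "c", start = seq(0, 9000, 1000),
                            end = seq(1000, 10000, 1000),
                            name = letters[1:10])
  scores <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100)
  out <- filter_pres(catalog, scores, method = "quantile",
                     weak_fraction = 0.3)
  expect_equal(sum(out$filtered_reason == "weak_signal", na.rm = TRUE), 3)
})

test_that("fully filtered catalogs raise an error", {
  catalog <- tibble::tibble(chrom = "c", start = 0, end = 1000, name = "a")
  excl <- tibble::tibble(chrom = "c", start = 0, end = 5000)
  expect_error(suppressWarnings(filter_pres(catalog, 1, excl)),
               "All elements")
})

test_that("distribution comparison returns medians and a two-sided p", {
  x <- c(1, 2, 3)
  res <- compare_distributions(x, x + 0.1)
  expect_true(res$p_value > 0.6)
  res2 <- compare_distributions(c(1, 2, 3), c(11, 12, 13))
  expect_equal(res2$p_value, perm_wilcox_p(c(1, 2, 3), c(11, 12, 13)))
  expect_equal(res2$median_x, 2)
  expect_equal(res2$median_y, 12)
  withr::with_seed(33, {
    a <- rnorm(135)
    b <- rnorm(135, mean = 1)
  })
  expect_lt(compare_distributions(a, b)$p_value, 1e-6)
  expect_error(compare_distributions(1:2, 1:5), "length >= 3")
})

test_that("RD and classes are invariant under per-library depth rescaling", {
  sim <- simulate_tracks(simulation_config(chrom_length = 6e5, n_pres = 12,
                                           seed = 17))
  sc <- score_pres(sim$catalog, sim$tracks)
  cl <- classify_pres(sc)
  tracks2 <- sim$tracks
  scale_by <- c(2, 0.5, 3, 1, 7, 0.25, 1.5, 4)
  tracks2$track <- purrr::map2(tracks2$track, scale_by, function(tr, k) {
    coverage_track(tr$values * k, chrom = tr$chrom, origin = tr$origin)
  })
  cl2 <- classify_pres(score_pres(sim$catalog, tracks2))
  expect_equal(cl2$rd, cl$rd)
  expect_equal(cl2$dep_class, cl$dep_class)
})

test_that("genotype means average replicates before the RD contrast", {
  catalog <- tibble::tibble(chrom = "chrS", start = 0, end = 10, name = "e")
  mk <- function(v) coverage_track(rep(v, 10), total_depth = 1e6)
  tracks <- tibble::tibble(
    genotype = rep(c("control", "mutant"), each = 2),
    replicate = c(1, 2, 1, 2),
    type = "chip",
    track = list(mk(4), mk(8), mk(2), mk(4))
  )
  cl <- classify_pres(score_pres(catalog, tracks))
  expect_equal(cl$score_control, 6)
  expect_equal(cl$score_mutant, 3)
  expect_equal(cl$rd, 2 * (3 - 6) / 9)
})
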