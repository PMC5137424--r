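small_config <- function(...) {
  simulation_config(chrom_length = 6e5, n_pres = 12, ...)
}

test_that("identical seeds give bit-identical simulations", {
  s1 <- simulate_tracks(small_config(seed = 5))
  s2 <- simulate_tracks(small_config(seed = 5))
  expect_identical(s1$truth, s2$truth)
  expect_identical(
    lapply(s1$tracks$track, `[[`, "values"),
    lapply(s2$tracks$track, `[[`, "values")
  )
  s3 <- simulate_tracks(small_config(seed = 6))
  expect_false(identical(s1$tracks$track[[1]]$values,
                         s3$tracks$track[[1]]$values))
})

test_that("impossible element placement raises a placement error", {
  expect_error(
    simulate_tracks(simulation_config(chrom_length = 1e5, n_pres = 10)),
    "25000 bp apart"
  )
})

test_that("no-enrichment configuration yields flat expected coverage", {
  cfg <- small_config(summit_amplitude_control = 1, amplitude_sigma = 0,
                      seed = 3)
  sim <- simulate_tracks(cfg)
  tr <- sim$tracks$track[[1]]  # control chip
  inside <- unlist(purrr::map2(sim$truth$start, sim$truth$end,
                               function(s, e) track_segment(tr, s, e)))
  outside_mean <- (sum(tr$values) - sum(inside)) /
    (track_length(tr) - length(inside))
  se <- sqrt(cfg$background_rate / length(inside))
  expect_lt(abs(mean(inside) - outside_mean), 3 * se)
})

test_that("class-wise summit coverage matches the generative expectation", {
  sim <- simulate_tracks(simulation_config(seed = 1))
  half_plateau <- sim$config$plateau_width %/% 2L
  chip_mut <- sim$tracks$track[sim$tracks$genotype == "mutant" &
                                 sim$tracks$type == "chip"]
  for (cls in c("dependent", "intermediate", "independent")) {
    rows <- sim$truth[sim$truth$class == cls, ]
    obs <- mean(unlist(lapply(chip_mut, function(tr) {
      purrr::map2(rows$summit - half_plateau, rows$summit + half_plateau,
                  function(s, e) track_segment(tr, s, e))
    })))
    expected <- mean(rows$mutant_summit_amplitude) *
      sim$config$background_rate
    expect_lt(abs(obs - expected) / expected, 0.10)
    # and the nominal per-class expectation under amplitude 20, bg 0.5
    nominal <- c(dependent = 1, intermediate = 4, independent = 9)[[cls]]
    expect_lt(abs(expected - nominal) / nominal, 0.5)
  }
})

test_that("equal attenuation in all classes centers RD on zero", {
  att <- c(dependent = 1, intermediate = 1, independent = 1)
  sim <- simulate_tracks(small_config(attenuation_by_class = att, seed = 9))
  cl <- classify_pres(score_pres(sim$catalog, sim$tracks))
  expect_lt(abs(median(cl$rd)), 0.15)
  expect_gt(mean(cl$dep_class == "independent"), 0.9)
})

test_that("depth factors scale expected coverage linearly", {
  k <- 3
  base <- small_config(seed = 13)
  scaled <- small_config(depth_factors = k, seed = 13)
  s1 <- simulate_tracks(base)
  s2 <- simulate_tracks(scaled)
  m1 <- mean(s1$tracks$track[[1]]$values)
  m2 <- mean(s2$tracks$track[[1]]$values)
  # large-window relative comparison: mean coverage scales by k
  expect_lt(abs(m2 / m1 - k), 0.02 * k)
})

test_that("true dependent elements have lower mutant/control summit ratios than independent ones", {
  sim <- simulate_tracks(simulation_config(seed = 2))
  cl <- classify_pres(score_pres(sim$catalog, sim$tracks))
  cl$truth <- sim$truth$class[match(cl$name, sim$truth$name)]
  dep <- cl$ratio[cl$truth == "dependent"]
  ind <- cl$ratio[cl$truth == "independent"]
  pairs <- outer(dep, ind, `<`)
  expect_gte(mean(pairs), 0.99)
})

test_that("input tracks are background-only", {
  sim <- simulate_tracks(small_config(seed = 4))
  inp <- sim$tracks$track[[which(sim$tracks$type == "input")[1]]]
  bg <- sim$config$background_rate
  expect_lt(abs(mean(inp$values) - bg),
            3 * sqrt(bg / track_length(inp)))
  # no elevation at elements
  inside <- unlist(purrr::map2(sim$truth$start, sim$truth$end,
                               function(s, e) track_segment(inp, s, e)))
  expect_lt(abs(mean(inside) - bg), 3 * sqrt(bg / length(inside)))
})

test_that("simulations export and re-import as text formats", {
  sim <- simulate_tracks(small_config(seed = 8))
  dir <- withr::local_tempdir()
  suppressMessages(write_simulation(sim, dir))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- suppressMessages(
    read_bedgraph(file.path(dir, "control_rep1_chip.bedgraph")))
  expect_equal(back$chrS$values, sim$tracks$track[[1]]$values)
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(sim$truth))
  cat_bed <- suppressMessages(read_bed(file.path(dir, "catalog.bed")))
  expect_equal(cat_bed$start, sim$catalog$start)
})

test_that("negative binomial noise is overdispersed relative to Poisson", {
  cfg <- small_config(noise = "negative_binomial", dispersion = 0.5,
                      seed = 10)
  sim <- simulate_tracks(cfg)
  inp <- sim$tracks$track[[which(sim$tracks$type == "input")[1]]]
  v <- var(inp$values)
  mu <- mean(inp$values)
  # var = mu + 0.5 mu^2 > mu
  expect_gt(v, mu * 1.15)
})
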