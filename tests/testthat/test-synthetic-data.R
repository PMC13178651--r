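test_that("simulations are reproducible from the seed and leave the RNG alone", {
  a <- simulate_tracks(n_beads = 4, seed = 123)
  b <- simulate_tracks(n_beads = 4, seed = 123)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)

  c1 <- simulate_clearance(seed = 9)
  c2 <- simulate_clearance(seed = 9)
  expect_identical(c1$frames, c2$frames)

  set.seed(555)
  before <- .Random.seed
  invisible(simulate_tracks(n_beads = 2, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("full elastic recovery zeroes the asymptotic net displacement", {
  sim <- simulate_tracks(n_beads = 1, noise_sd = 0, drift = c(0, 0),
                         recovery_fraction = 1, recoil_tau = 0.05, seed = 1)
  expect_equal(sim$truth$net_displacement, 0)
  m <- pulse_metrics(sim$tracks, pulse_protocol())
  # recoil_tau of 0.05 s over a 5 s recovery: recoil is complete
  expect_equal(m$net_displacement, 0, tolerance = 1e-6)
})

test_that("zero recovery makes net displacement equal pulse displacement", {
  sim <- simulate_tracks(n_beads = 1, noise_sd = 0, drift = c(0, 0),
                         recovery_fraction = 0, seed = 1)
  expect_equal(sim$truth$net_displacement, sim$truth$pulse_displacement)
  m <- pulse_metrics(sim$tracks, pulse_protocol())
  expect_equal(m$net_displacement, m$pulse_displacement, tolerance = 1e-9)
})

test_that("noise-zero track analysis equals ground truth end to end", {
  proto <- pulse_protocol()
  sim <- simulate_tracks(n_beads = 12, noise_sd = 0, drift = c(0.4, -0.1),
                         recoil_tau = 0.3, seed = 42)
  res <- analyze_tracks(sim$tracks, proto)
  ens <- res$ensemble
  get <- function(metric, col) ens[[col]][ens$metric == metric]
  expect_equal(get("pulse_displacement", "mean"),
               sim$truth$pulse_displacement, tolerance = 1e-6)
  expect_equal(get("net_displacement", "mean"),
               sim$truth$net_displacement_at_end, tolerance = 1e-6)
  expect_equal(get("pulse_displacement", "sd"), 0, tolerance = 1e-6)
  # recoil essentially complete at recoil_tau = 0.3 s, so the asymptotic
  # truth is met too
  expect_equal(get("net_displacement", "mean"),
               sim$truth$net_displacement, tolerance = 1e-4)
  expect_equal(c(res$drift$vx, res$drift$vy), c(0.4, -0.1), tolerance = 1e-9)
})

test_that("noise-zero clearance analysis equals ground truth end to end", {
  t <- seq(0, 15, by = 0.5)
  f <- 0.6; kf <- 0.25; ks <- 0.01
  r <- f * exp(-kf * t) + (1 - f) * exp(-ks * t)
  frames <- gamma_series(t, 3000 * r)
  res <- analyze_clearance(frames)
  sim <- simulate_clearance(fast_fraction = f, k_fast = kf, k_slow = ks,
                            seed = 1)
  expect_equal(res$rate$rate, sim$truth$initial_rate, tolerance = 1e-9)
  expect_equal(res$fit$fast_fraction, f, tolerance = 1e-6)
  expect_equal(res$fit$k_fast, kf, tolerance = 1e-6)
  expect_equal(res$fit$k_slow, ks, tolerance = 1e-4)
})

test_that("degenerate clearance regimes behave as specified", {
  # no clearance at all: counts stay Poisson around baseline
  sim <- simulate_clearance(fast_fraction = 0, k_fast = 0, k_slow = 0,
                            seed = 77)
  curve <- clearance_curve(sim$frames)
  expect_lt(abs(mean(curve$percent_cleared)), 10)
  expect_equal(sim$truth$initial_rate, 0)

  # pure single exponential (fast_fraction 1)
  sim1 <- simulate_clearance(fast_fraction = 1, k_fast = 0.3, k_slow = 0,
                             seed = 78)
  t <- sim1$frames$t_min
  r_true <- exp(-0.3 * t)
  noiseless <- analyze_clearance(gamma_series(t, 3000 * r_true))
  k_dom <- if (noiseless$fit$fast_fraction > 0.5) noiseless$fit$k_fast else
    noiseless$fit$k_slow
  expect_equal(k_dom, 0.3, tolerance = 1e-3)
  expect_true(noiseless$fit$degenerate)
})

test_that("frequency cohort generator matches its recorded truth", {
  sim0 <- simulate_frequency_cohort(n_animals = 10, noise_sd = 0, seed = 4)
  fr <- frequency_regression(sim0$samples$bpm, sim0$samples$rate)
  expect_equal(fr$slope, sim0$truth$slope, tolerance = 1e-9)
  expect_equal(fr$intercept, sim0$truth$intercept, tolerance = 1e-9)
  expect_equal(fr$r_squared, 1, tolerance = 1e-9)

  # a zero-slope cohort yields slope estimates centred on zero
  slopes <- vapply(1:100, function(i) {
    s <- simulate_frequency_cohort(n_animals = 12, slope = 0, noise_sd = 0.5,
                                   seed = 6000 + i)
    frequency_regression(s$samples$bpm, s$samples$rate)$slope
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 3 * se)

  expect_error(simulate_frequency_cohort(bpm_range = c(100, 100)),
               "increasing")
  expect_error(simulate_frequency_cohort(n_animals = 2), ">= 3")
})

test_that("recovered cohort slope is unbiased near the R^2 ~ 0.86 regime", {
  slopes <- vapply(1:100, function(i) {
    s <- simulate_frequency_cohort(seed = 7000 + i)
    frequency_regression(s$samples$bpm, s$samples$rate)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.08) / 0.08, 0.10)
  r2 <- vapply(1:50, function(i) {
    s <- simulate_frequency_cohort(seed = 7100 + i)
    frequency_regression(s$samples$bpm, s$samples$rate)$r_squared
  }, numeric(1))
  expect_gt(mean(r2), 0.7)
  expect_lt(mean(r2), 0.95)
})

test_that("ground-truth records serialize with everything needed downstream", {
  sim <- simulate_tracks(n_beads = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$net_displacement, sim$truth$net_displacement)
  expect_equal(back$protocol$t_pulse_end, 10)
  expect_equal(back$seed, 3)

  simc <- simulate_clearance(seed = 3)
  expect_true(all(c("initial_rate", "k_fast", "k_slow", "fast_fraction",
                    "baseline_counts", "shifts") %in% names(simc$truth)))
})

test_that("simulator parameter validation rejects impossible regimes", {
  expect_error(simulate_tracks(recovery_fraction = 1.5), "recovery_fraction")
  expect_error(simulate_tracks(fast_tau = 0), "time constants")
  expect_error(simulate_tracks(noise_sd = -1), "noise_sd")
  expect_error(simulate_clearance(k_fast = 0.01, k_slow = 0.5), "k_fast >= k_slow")
  expect_error(simulate_clearance(baseline_counts = 0), "> 0")
})
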