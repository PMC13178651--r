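test_that("track tables round-trip through the TrackMate CSV dialect", {
  sim <- simulate_tracks(n_beads = 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, path)
  back <- read_tracks(path, frame_rate = 100)
  expect_equal(back$x, sim$tracks$x, tolerance = 1e-9)
  expect_equal(back$y, sim$tracks$y, tolerance = 1e-9)
  expect_equal(back$frame, sim$tracks$frame)
  expect_equal(unique(back$track_id), unique(sim$tracks$track_id))
})

test_that("TrackMate sub-header rows are tolerated and bad files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "TRACK_ID,FRAME,POSITION_X,POSITION_Y,POSITION_T",
    "Track ID,Frame,X,Y,T",          # human-readable sub-header
    "Track ID,Frame,(um),(um),(s)",  # units sub-header
    "1,0,0.0,0.0,0.00",
    "1,1,1.0,0.5,0.01",
    "2,0,5.0,5.0,0.00",
    "2,1,5.5,5.0,0.01"), path)
  tr <- read_tracks(path, frame_rate = 100)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(nrow(tr), 4)

  # missing required column named in the error
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TRACK_ID,FRAME,POSITION_Y", "1,0,0"), path2)
  expect_error(read_tracks(path2), "POSITION_X")

  # duplicate (track, frame) row
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TRACK_ID,FRAME,POSITION_X,POSITION_Y",
               "1,0,0,0", "1,0,1,1"), path3)
  expect_error(read_tracks(path3), "duplicate")
})

test_that("incomplete tracks are excluded and bookkeeping is conserved", {
  proto <- default_protocol()
  full <- piecewise_bead("full")
  t_short <- seq(0, 9, by = 0.1)
  short <- make_track("short", t_short, x = t_short, y = 0 * t_short,
                      frame_rate = 10)
  t_late <- seq(2, 15, by = 0.1)
  late <- make_track("late", t_late, x = 0 * t_late, y = 0 * t_late,
                     frame_rate = 10)
  all_tracks <- bind_tracks(full, short, late)
  flt <- filter_complete_tracks(all_tracks, proto)
  expect_equal(unique(flt$kept$track_id), "full")
  expect_setequal(flt$excluded$track_id, c("short", "late"))
  expect_equal(length(unique(all_tracks$track_id)),
               length(unique(flt$kept$track_id)) + nrow(flt$excluded))

  empty <- glt_tracks(character(), integer(), numeric(), numeric())
  flt0 <- filter_complete_tracks(empty, proto)
  expect_equal(nrow(flt0$kept), 0)
  expect_equal(nrow(flt0$excluded), 0)
})

test_that("ciliary drift is recovered exactly from noiseless translation", {
  proto <- default_protocol()
  t <- seq(0, 15, by = 0.1)
  stationary <- bind_tracks(
    make_track("a", t, 0 * t, 0 * t, 10),
    make_track("b", t, 3 + 0 * t, 1 + 0 * t, 10))
  d0 <- suppressWarnings(estimate_ciliary_drift(stationary, proto))
  expect_equal(c(d0$vx, d0$vy), c(0, 0))

  moving <- bind_tracks(
    make_track("a", t, 1 * t, 2 * t, 10),
    make_track("b", t, 10 + 1 * t, -4 + 2 * t, 10))
  d1 <- suppressWarnings(estimate_ciliary_drift(moving, proto))
  expect_equal(c(d1$vx, d1$vy), c(1, 2), tolerance = 1e-12)

  # insufficient in-window data
  t_out <- seq(6, 15, by = 0.1)
  outside <- make_track("c", t_out, t_out, t_out, 10)
  expect_error(suppressWarnings(estimate_ciliary_drift(outside, proto)),
               "drift window")
})

test_that("noisy drift estimate lands within 3 SE of the generating truth", {
  truth <- c(0.5, -0.3)
  sim <- simulate_tracks(n_beads = 15, drift = truth, noise_sd = 0.05,
                         seed = 202)
  est <- suppressWarnings(estimate_ciliary_drift(sim$tracks, default_protocol()))
  # SE of an endpoint-difference velocity over a 5 s window, 15 beads:
  # sd = sqrt(2) * noise / window per bead
  se <- sqrt(2) * 0.05 / 5 / sqrt(15)
  expect_lt(abs(est$vx - truth[1]), 3 * se)
  expect_lt(abs(est$vy - truth[2]), 3 * se)
})

test_that("drift subtraction is an identity at zero drift and inverts pure drift", {
  sim <- simulate_tracks(n_beads = 3, seed = 5)
  same <- subtract_drift(sim$tracks, c(0, 0))
  expect_equal(same$x, sim$tracks$x)
  expect_equal(same$y, sim$tracks$y)

  t <- seq(0, 15, by = 0.1)
  pure <- make_track("p", t, 2 * t, -1 * t, 10)
  corr <- subtract_drift(pure, c(2, -1))
  expect_equal(corr$x, rep(0, length(t)), tolerance = 1e-9)
  expect_equal(corr$y, rep(0, length(t)), tolerance = 1e-9)

  # subtract then re-add restores the original coordinates
  back <- subtract_drift(corr, c(-2, 1))
  expect_equal(back$x, pure$x, tolerance = 1e-9)
  expect_equal(back$y, pure$y, tolerance = 1e-9)
})

test_that("point-to-point velocities match uniform motion and locate the pulse", {
  t <- seq(0, 1, by = 0.01)
  uni <- make_track("u", t, 10 * t, 0 * t, 100)
  v <- instantaneous_velocities(uni)
  expect_equal(v$speed, rep(10, length(t) - 1), tolerance = 1e-9)

  still <- make_track("s", t, 0 * t, 0 * t, 100)
  expect_equal(instantaneous_velocities(still)$speed, rep(0, length(t) - 1))

  one <- make_track("o", 0, 0, 0, 100)
  expect_error(instantaneous_velocities(one), "2 spots")

  sim <- simulate_tracks(n_beads = 1, noise_sd = 0, drift = c(0, 0), seed = 1)
  vv <- instantaneous_velocities(sim$tracks)
  t_peak <- vv$t[which.max(vv$speed)]
  expect_gte(t_peak, 5)
  expect_lte(t_peak, 10)
})

test_that("pulse metrics reproduce the forced piecewise example", {
  m <- pulse_metrics(piecewise_bead(), default_protocol())
  expect_equal(m$pulse_displacement, 20, tolerance = 1e-9)
  expect_equal(m$recoil_distance, -5, tolerance = 1e-9)
  expect_equal(m$net_displacement, 15, tolerance = 1e-9)
  expect_equal(m$percent_recovery, 25, tolerance = 1e-9)

  t <- seq(0, 15, by = 0.1)
  still <- make_track("s", t, 0 * t, 0 * t, 10)
  m0 <- pulse_metrics(still, default_protocol())
  expect_equal(m0$pulse_displacement, 0)
  expect_equal(m0$net_displacement, 0)
  expect_equal(m0$percent_recovery, 0)  # floor rule, no 0/0

  t_short <- seq(0, 9, by = 0.1)
  incomplete <- make_track("i", t_short, t_short, 0 * t_short, 10)
  expect_error(pulse_metrics(incomplete, default_protocol()), "complete")
})

test_that("net displacement equals pulse plus recoil for every track (signed)", {
  sim <- simulate_tracks(n_beads = 20, noise_sd = 0.3, seed = 77)
  mets <- track_metrics(sim$tracks, default_protocol())
  expect_equal(mets$net_displacement,
               mets$pulse_displacement + mets$recoil_distance,
               tolerance = 1e-9)
})

test_that("metrics are invariant to an added constant drift after correction", {
  proto <- default_protocol()
  sim <- simulate_tracks(n_beads = 12, drift = c(0, 0), noise_sd = 0,
                         seed = 31)
  base <- track_metrics(sim$tracks, proto, drift = c(0, 0))

  added <- c(0.7, -0.4)
  df <- as.data.frame(sim$tracks)
  df$x <- df$x + added[1] * df$t
  df$y <- df$y + added[2] * df$t
  drifted <- glt_tracks(df$track_id, df$frame, df$x, df$y, frame_rate = 100)
  est <- suppressWarnings(estimate_ciliary_drift(drifted, proto))
  expect_equal(c(est$vx, est$vy), added, tolerance = 1e-9)
  corrected <- track_metrics(drifted, proto, drift = est)
  for (col in c("pulse_displacement", "recoil_distance", "net_displacement",
                "percent_recovery")) {
    expect_equal(corrected[[col]], base[[col]], tolerance = 1e-6)
  }
})

test_that("projected metrics are invariant to a joint rotation of axes", {
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sim <- simulate_tracks(n_beads = 8, noise_sd = 0.1, seed = 99)
  proto <- default_protocol()
  base <- track_metrics(sim$tracks, proto, drift = c(0, 0))

  xy <- R %*% rbind(sim$tracks$x, sim$tracks$y)
  rot <- glt_tracks(sim$tracks$track_id, sim$tracks$frame, xy[1, ], xy[2, ],
                    frame_rate = 100)
  proto_rot <- pulse_protocol(axis = as.numeric(R %*% proto$axis))
  rot_m <- track_metrics(rot, proto_rot, drift = c(0, 0))
  for (col in c("pulse_displacement", "recoil_distance", "net_displacement",
                "percent_recovery", "peak_velocity")) {
    expect_equal(rot_m[[col]], base[[col]], tolerance = 1e-9)
  }
})

test_that("ensemble statistics summarize and conserve track counts", {
  m1 <- pulse_metrics(piecewise_bead("a"), default_protocol())
  reps <- do.call(rbind, lapply(1:5, function(i) m1))
  ens <- ensemble_metrics(reps)
  expect_equal(ens$mean[ens$metric == "net_displacement"], 15)
  expect_true(all(ens$sd == 0))
  expect_true(all(ens$n == 5))

  two <- rbind(m1, m1)
  two$net_displacement <- c(10, 14)
  ens2 <- ensemble_metrics(two)
  expect_equal(ens2$mean[ens2$metric == "net_displacement"], 12)

  expect_warning(ensemble_metrics(m1), "single track")
  expect_error(ensemble_metrics(m1[0, ]), "at least one row")
})

test_that("full pipeline excludes incomplete tracks from all statistics", {
  sim <- simulate_tracks(n_beads = 12, seed = 8)
  t_short <- seq(0, 8, by = 0.01)
  short <- make_track("dropout", t_short, t_short, 0 * t_short, 100)
  mixed <- bind_tracks(sim$tracks, short)
  res <- analyze_tracks(mixed, default_protocol())
  expect_equal(attr(res$ensemble, "n_tracks"), 12)
  expect_equal(attr(res$ensemble, "n_excluded"), 1)
  expect_false("dropout" %in% res$metrics$track_id)
})
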