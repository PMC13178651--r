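# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Along-axis displacement model of one bead over the pulse protocol:
# zero before the pulse; during the pulse a saturating-exponential fast
# phase plus linear steady creep; after the pulse an exponential recoil
# removing `recovery_fraction` of the pulse displacement.
bead_displacement <- function(t, protocol, fast_amplitude, fast_tau,
                              steady_velocity, recovery_fraction, recoil_tau) {
  t1 <- protocol$t_pulse_start
  t2 <- protocol$t_pulse_end
  s_pulse <- fast_amplitude * (1 - exp(-(t2 - t1) / fast_tau)) +
    steady_velocity * (t2 - t1)
  s <- numeric(length(t))
  during <- t > t1 & t <= t2
  after <- t > t2
  s[during] <- fast_amplitude * (1 - exp(-(t[during] - t1) / fast_tau)) +
    steady_velocity * (t[during] - t1)
  s[after] <- s_pulse - recovery_fraction * s_pulse *
    (1 - exp(-(t[after] - t2) / recoil_tau))
  s
}

#' Simulate bead trajectories under a breath-mimicking airflow pulse
#'
#' Generates a field of mucus-embedded bead tracks with the kinematic
#' structure the track analysis assumes: no airflow-driven motion during
#' the pre-pulse phase; during the pulse a biphasic response (an initial
#' rapid, saturating displacement of amplitude `fast_amplitude` and time
#' constant `fast_tau`, plus a slower steady creep at `steady_velocity`);
#' after the pulse an exponential elastic recoil that takes back
#' `recovery_fraction` of the pulse displacement with time constant
#' `recoil_tau`. Constant-velocity ciliary drift acts on both axes
#' throughout, and i.i.d. Gaussian localization noise is added to every
#' spot. This is a phenomenological kinematic model (chosen for analytic
#' ground truth), not a rheological one.
#'
#' @param n_beads number of beads in the field. Default 15 (a typical
#'   field holds 10-20).
#' @param protocol a [pulse_protocol()]. Default: 5 s no flow, 5 s pulse,
#'   5 s recovery.
#' @param frame_rate acquisition rate, fps. Default 100.
#' @param drift ciliary drift vector `(vx, vy)`, um/s. Default
#'   `c(0.3, -0.2)` (slow, sub-um/s residual ciliary motion).
#' @param fast_amplitude amplitude of the rapid initial displacement, um.
#' @param fast_tau time constant of the rapid phase, s.
#' @param steady_velocity steady-state creep velocity during the pulse,
#'   um/s.
#' @param recovery_fraction fraction (0-1) of the pulse displacement taken
#'   back by elastic recoil.
#' @param recoil_tau recoil time constant, s.
#' @param noise_sd localization noise SD per coordinate, um. Default 0.1.
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return A list: `tracks` (a `glt_tracks` table) and `truth`, a list of
#'   class `glt_ground_truth` holding every generating parameter plus the
#'   derived true metrics: `pulse_displacement`, `recoil_distance`,
#'   `net_displacement` (asymptotic, `(1 - recovery_fraction) * pulse`),
#'   and `net_displacement_at_end` (at the last recorded frame).
#' @export
#' @examples
#' sim <- simulate_tracks(n_beads = 5, seed = 1)
#' sim$truth$net_displacement
simulate_tracks <- function(n_beads = 15, protocol = pulse_protocol(),
                            frame_rate = 100, drift = c(0.3, -0.2),
                            fast_amplitude = 15, fast_tau = 0.5,
                            steady_velocity = 4, recovery_fraction = 0.4,
                            recoil_tau = 0.5, noise_sd = 0.1, seed = NULL) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  if (n_beads < 1) stop("`n_beads` must be >= 1", call. = FALSE)
  if (fast_tau <= 0 || recoil_tau <= 0) {
    stop("time constants must be > 0", call. = FALSE)
  }
  if (recovery_fraction < 0 || recovery_fraction > 1) {
    stop("`recovery_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(drift) != 2 || any(!is.finite(drift))) {
    stop("`drift` must be a finite 2-vector (um/s)", call. = FALSE)
  }

  frames <- seq(round(protocol$t_pre_start * frame_rate),
                round(protocol$t_end * frame_rate))
  t <- frames / frame_rate
  s <- bead_displacement(t, protocol, fast_amplitude, fast_tau,
                         steady_velocity, recovery_fraction, recoil_tau)
  ax <- protocol$axis

  tracks <- with_seed(seed, {
    pieces <- vector("list", n_beads)
    for (b in seq_len(n_beads)) {
      x0 <- stats::runif(1, 0, 200)
      y0 <- stats::runif(1, 0, 200)
      x <- x0 + ax[1] * s + drift[1] * (t - t[1]) +
        stats::rnorm(length(t), 0, noise_sd)
      y <- y0 + ax[2] * s + drift[2] * (t - t[1]) +
        stats::rnorm(length(t), 0, noise_sd)
      pieces[[b]] <- data.frame(track_id = sprintf("bead_%02d", b),
                                frame = frames, t = t, x = x, y = y,
                                stringsAsFactors = FALSE)
    }
    new_glt_tracks(do.call(rbind, pieces), frame_rate)
  })

  dur <- protocol$t_pulse_end - protocol$t_pulse_start
  s_pulse <- fast_amplitude * (1 - exp(-dur / fast_tau)) + steady_velocity * dur
  truth <- structure(list(
    kind = "tracks",
    n_beads = n_beads, frame_rate = frame_rate, drift = drift,
    fast_amplitude = fast_amplitude, fast_tau = fast_tau,
    steady_velocity = steady_velocity,
    recovery_fraction = recovery_fraction, recoil_tau = recoil_tau,
    noise_sd = noise_sd, seed = seed,
    protocol = unclass(protocol),
    pulse_displacement = s_pulse,
    recoil_distance = s[length(s)] - s_pulse,
    net_displacement = (1 - recovery_fraction) * s_pulse,
    net_displacement_at_end = s[length(s)],
    percent_recovery = recovery_fraction * 100 *
      (1 - exp(-(protocol$t_end - protocol$t_pulse_end) / recoil_tau))
  ), class = "glt_ground_truth")
  list(tracks = tracks, truth = truth)
}

#' Simulate a gamma-camera clearance series
#'
#' Generates ROI count frames with the structure the clearance analysis
#' assumes: the retained tracer fraction follows the two-compartment model
#' `r(t) = F exp(-k_fast t) + (1 - F) exp(-k_slow t)`, observed counts are
#' Poisson with mean `baseline_counts * r(t)`, and the fiducial markers
#' are displaced by a per-frame rigid animal motion plus Gaussian
#' localization jitter.
#'
#' @param baseline_counts expected photopeak counts at deposition.
#'   Default 3000, a typical acquisition.
#' @param fast_fraction fraction cleared through the fast compartment.
#' @param k_fast,k_slow fast/slow rate constants, 1/min
#'   (`k_fast >= k_slow >= 0`).
#' @param frame_times acquisition times, minutes. Default every 30 s for
#'   15 min.
#' @param fiducial_layout n x 2 matrix of true fiducial positions
#'   (arbitrary image units). Default: 3 well-separated markers.
#' @param animal_motion_sd SD of the per-frame rigid translation (frame 1
#'   is the reference and is not displaced). Default 0.5.
#' @param fiducial_jitter_sd SD of per-marker localization jitter.
#'   Default 0.1.
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return A list: `frames` (a `gamma_series`) and `truth`
#'   (`glt_ground_truth`) holding the parameters, the applied per-frame
#'   shifts, and `initial_rate` — the OLS slope of the noiseless percent-
#'   cleared curve `100 * (1 - r(t))` over the frames in the 0-5 min
#'   window, i.e. the value [initial_rate()] estimates.
#' @export
#' @examples
#' sim <- simulate_clearance(seed = 1)
#' sim$truth$initial_rate
simulate_clearance <- function(baseline_counts = 3000, fast_fraction = 0.6,
                               k_fast = 0.25, k_slow = 0.01,
                               frame_times = seq(0, 15, by = 0.5),
                               fiducial_layout = rbind(c(-8, -8), c(8, -8), c(0, 8)),
                               animal_motion_sd = 0.5,
                               fiducial_jitter_sd = 0.1, seed = NULL) {
  if (baseline_counts <= 0) stop("`baseline_counts` must be > 0", call. = FALSE)
  if (k_fast < 0 || k_slow < 0 || k_fast < k_slow) {
    stop("need k_fast >= k_slow >= 0", call. = FALSE)
  }
  if (fast_fraction < 0 || fast_fraction > 1) {
    stop("`fast_fraction` must be in [0, 1]", call. = FALSE)
  }
  t <- frame_times - frame_times[1]
  r <- fast_fraction * exp(-k_fast * t) + (1 - fast_fraction) * exp(-k_slow * t)
  nf <- nrow(fiducial_layout)
  nt <- length(t)

  out <- with_seed(seed, {
    counts <- stats::rpois(nt, baseline_counts * r)
    shifts <- cbind(c(0, stats::rnorm(nt - 1, 0, animal_motion_sd)),
                    c(0, stats::rnorm(nt - 1, 0, animal_motion_sd)))
    fids <- lapply(seq_len(nt), function(k) {
      fiducial_layout +
        matrix(shifts[k, ], nf, 2, byrow = TRUE) +
        matrix(stats::rnorm(2 * nf, 0, fiducial_jitter_sd), nf, 2)
    })
    list(counts = counts, shifts = shifts, fids = fids)
  })

  frames <- gamma_series(frame_times, out$counts, fiducials = out$fids)
  inw <- t >= 0 & t <= 5
  pc_true <- 100 * (1 - r)
  true_rate <- unname(stats::coef(stats::lm(pc_true[inw] ~ t[inw]))[2])
  truth <- structure(list(
    kind = "clearance",
    baseline_counts = baseline_counts, fast_fraction = fast_fraction,
    k_fast = k_fast, k_slow = k_slow, frame_times = frame_times,
    animal_motion_sd = animal_motion_sd,
    fiducial_jitter_sd = fiducial_jitter_sd, seed = seed,
    shifts = out$shifts,
    initial_rate = true_rate
  ), class = "glt_ground_truth")
  list(frames = frames, truth = truth)
}

#' Simulate a clearance-versus-breathing-frequency cohort
#'
#' Draws breathing frequencies uniformly over `bpm_range` and generates
#' initial clearance rates linear in frequency plus Gaussian noise, the
#' regime in which clearance scales with the number of airflow pulses
#' delivered per minute.
#'
#' @param n_animals cohort size (>= 3).
#' @param slope true slope, %/min per bpm. Default 0.08.
#' @param intercept true intercept, %/min. Default 1.
#' @param bpm_range length-2 range of breathing frequencies, breaths/min.
#'   Default `c(60, 130)` (isoflurane through ketamine/xylazine regimes).
#' @param noise_sd residual SD of the rate, %/min. Default 0.65, which
#'   puts the expected R-squared near 0.86 for the default slope and
#'   range.
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return A list: `samples` (data.frame of `bpm`, `rate`) and `truth`
#'   (`glt_ground_truth` with the generating parameters).
#' @export
simulate_frequency_cohort <- function(n_animals = 20, slope = 0.08,
                                      intercept = 1, bpm_range = c(60, 130),
                                      noise_sd = 0.65, seed = NULL) {
  if (n_animals < 3) stop("`n_animals` must be >= 3", call. = FALSE)
  if (length(bpm_range) != 2 || bpm_range[2] <= bpm_range[1]) {
    stop("`bpm_range` must be an increasing length-2 range", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  samples <- with_seed(seed, {
    bpm <- stats::runif(n_animals, bpm_range[1], bpm_range[2])
    rate <- slope * bpm + intercept + stats::rnorm(n_animals, 0, noise_sd)
    data.frame(bpm = bpm, rate = rate)
  })
  truth <- structure(list(
    kind = "frequency_cohort",
    n_animals = n_animals, slope = slope, intercept = intercept,
    bpm_range = bpm_range, noise_sd = noise_sd, seed = seed
  ), class = "glt_ground_truth")
  list(samples = samples, truth = truth)
}

#' @export
print.glt_ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth (%s simulation)\n", x$kind))
  flat <- x[vapply(x, function(v) is.numeric(v) && length(v) <= 2, logical(1))]
  for (nm in names(flat)) {
    cat(sprintf("  %s: %s\n", nm, paste(signif(flat[[nm]], 6), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a ground-truth record as JSON
#'
#' Writes the generating parameters and derived true metrics alongside a
#' simulated dataset, sufficient to recompute every metric the analysis
#' modules produce.
#'
#' @param truth a `glt_ground_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "glt_ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
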