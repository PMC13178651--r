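#' Assemble a gamma-camera frame series
#'
#' One row per acquisition frame: time in minutes, region-of-interest
#' (ROI) counts within the photopeak, and optionally the image positions
#' of subdermal fiducial markers used to coregister frames when the
#' animal moves.
#'
#' @param t_min frame times, minutes, nondecreasing.
#' @param roi_counts nonnegative ROI counts per frame.
#' @param fiducials optional list (one element per frame) of n x 2
#'   matrices of fiducial (x, y) positions, same marker count and order in
#'   every frame; or a single n x 2 matrix reused for all frames.
#' @return A data.frame of class `gamma_series` with columns `t_min`,
#'   `roi_counts` and, when fiducials are given, `fid<i>_x` / `fid<i>_y`.
#' @export
gamma_series <- function(t_min, roi_counts, fiducials = NULL) {
  if (length(t_min) != length(roi_counts)) {
    stop("`t_min` and `roi_counts` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(t_min)) || any(diff(t_min) < 0)) {
    stop("`t_min` must be finite and nondecreasing", call. = FALSE)
  }
  if (any(!is.finite(roi_counts)) || any(roi_counts < 0)) {
    stop("`roi_counts` must be finite and nonnegative", call. = FALSE)
  }
  df <- data.frame(t_min = t_min, roi_counts = roi_counts)
  if (!is.null(fiducials)) {
    if (is.matrix(fiducials)) {
      fiducials <- rep(list(fiducials), length(t_min))
    }
    if (length(fiducials) != length(t_min)) {
      stop("`fiducials` must have one matrix per frame", call. = FALSE)
    }
    nf <- nrow(fiducials[[1]])
    for (k in seq_along(fiducials)) {
      m <- fiducials[[k]]
      if (!is.matrix(m) || ncol(m) != 2 || nrow(m) != nf) {
        stop("inconsistent fiducial count or shape at frame ", k, call. = FALSE)
      }
    }
    for (i in seq_len(nf)) {
      df[[paste0("fid", i, "_x")]] <- vapply(fiducials, function(m) m[i, 1], numeric(1))
      df[[paste0("fid", i, "_y")]] <- vapply(fiducials, function(m) m[i, 2], numeric(1))
    }
  }
  class(df) <- c("gamma_series", "data.frame")
  df
}

#' Read a gamma-camera series from a delimited file
#'
#' Expects columns `t_min`, `roi_counts` and optional fiducial columns
#' `fid1_x`, `fid1_y`, `fid2_x`, ... (CSV or TSV; separator auto-detected).
#'
#' @param path input file path.
#' @return A `gamma_series` data.frame.
#' @export
read_gamma_series <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  for (col in c("t_min", "roi_counts")) {
    if (!(col %in% names(df))) {
      stop(sprintf("required column '%s' not found in %s", col, path),
           call. = FALSE)
    }
  }
  fidcols <- grep("^fid[0-9]+_[xy]$", names(df), value = TRUE)
  out <- gamma_series(df$t_min, df$roi_counts)
  for (cc in fidcols) out[[cc]] <- df[[cc]]
  out
}

fiducial_matrix <- function(frames, frame_row) {
  xs <- grep("^fid[0-9]+_x$", names(frames), value = TRUE)
  if (length(xs) == 0) return(NULL)
  idx <- sort(as.integer(sub("^fid([0-9]+)_x$", "\\1", xs)))
  m <- cbind(
    vapply(idx, function(i) frames[[paste0("fid", i, "_x")]][frame_row], numeric(1)),
    vapply(idx, function(i) frames[[paste0("fid", i, "_y")]][frame_row], numeric(1))
  )
  m
}

#' Coregister gamma-camera frames by their fiducial markers
#'
#' Animal movement between acquisitions shifts the image rigidly; the
#' subdermal point-source fiducials implanted before tracer deposition
#' record that shift. The per-frame rigid translation is estimated as the
#' displacement of the fiducial centroid relative to the first frame
#' (markers are assumed well separated with stable ordering, so no
#' matching step is needed) and is stored in columns `reg_dx`, `reg_dy` —
#' the amount by which the ROI definition must be shifted to follow the
#' animal.
#'
#' @param frames a `gamma_series` with >= 1 fiducial per frame.
#' @return The same `gamma_series` with `reg_dx`, `reg_dy` columns added.
#' @export
register_frames <- function(frames) {
  stopifnot(inherits(frames, "gamma_series"))
  xs <- grep("^fid[0-9]+_x$", names(frames), value = TRUE)
  ys <- grep("^fid[0-9]+_y$", names(frames), value = TRUE)
  if (length(xs) == 0 || length(xs) != length(ys)) {
    stop("frames carry no consistent fiducial columns", call. = FALSE)
  }
  fid <- as.matrix(frames[, c(xs, ys)])
  if (anyNA(fid)) {
    stop("fiducial count mismatch across frames (missing coordinates)",
         call. = FALSE)
  }
  cx <- rowMeans(frames[, xs, drop = FALSE])
  cy <- rowMeans(frames[, ys, drop = FALSE])
  frames$reg_dx <- cx - cx[1]
  frames$reg_dy <- cy - cy[1]
  frames
}

#' Percent-cleared curve from ROI counts
#'
#' Converts the ROI count series into the percentage of deposited tracer
#' cleared from the airway: `100 * (1 - counts(t) / counts(0))`. Counts may
#' optionally be corrected for radioactive decay of the tracer before the
#' ratio (Tc-99m half-life 6.01 h; over a 15 min study the correction is
#' < 3%, so it is off by default).
#'
#' @param frames a `gamma_series` (or any data.frame with `t_min` and
#'   `roi_counts`); >= 2 frames, baseline counts > 0.
#' @param decay_correct logical; divide counts by the decay factor
#'   `2^(-t/T_half)` before normalizing. Default `FALSE`.
#' @param half_life_h tracer half-life in hours. Default 6.01 (Tc-99m).
#' @param background constant background counts subtracted from every
#'   frame before normalization. Default 0.
#' @return A data.frame of class `clearance_curve` with columns `t_min`
#'   and `percent_cleared`; baseline counts kept as attribute
#'   `baseline_counts`.
#' @export
clearance_curve <- function(frames, decay_correct = FALSE,
                            half_life_h = 6.01, background = 0) {
  if (!is.data.frame(frames) ||
      !all(c("t_min", "roi_counts") %in% names(frames))) {
    stop("`frames` must have columns `t_min` and `roi_counts`", call. = FALSE)
  }
  if (nrow(frames) < 2) stop("need >= 2 frames", call. = FALSE)
  t <- frames$t_min
  counts <- frames$roi_counts - background
  if (decay_correct) {
    counts <- counts / 2^(-(t - t[1]) / (half_life_h * 60))
  }
  baseline <- counts[1]
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline (first-frame) counts must be > 0", call. = FALSE)
  }
  pc <- 100 * (1 - counts / baseline)
  if (any(pc < -5)) {
    warning("percent cleared below -5% at ", sum(pc < -5),
            " frame(s); check baseline and background")
  }
  out <- data.frame(t_min = t, percent_cleared = pc)
  attr(out, "baseline_counts") <- baseline
  attr(out, "decay_corrected") <- decay_correct
  class(out) <- c("clearance_curve", "data.frame")
  out
}

#' @export
print.clearance_curve <- function(x, ...) {
  cat(sprintf(
    "Clearance curve: %d frames over %g min, baseline %.0f counts%s\n",
    nrow(x), max(x$t_min) - min(x$t_min), attr(x, "baseline_counts"),
    if (isTRUE(attr(x, "decay_corrected"))) " (decay-corrected)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Initial clearance rate over a time window
#'
#' The initial clearance rate in %/min over a window (0-5 min by
#' convention), computed as the ordinary least-squares slope of percent
#' cleared against time restricted to the window. An endpoint variant
#' (difference over the window divided by its span) is available; the
#' regression slope is the default because it is robust to frame-timing
#' jitter.
#'
#' @param curve a [clearance_curve()].
#' @param window numeric length-2 `(t_from, t_to)`, minutes. Default
#'   `c(0, 5)`.
#' @param method `"slope"` (OLS, default) or `"endpoint"`.
#' @return A list of class `clearance_rate`: `rate` (%/min), `window`,
#'   `n` (frames used), `method`.
#' @export
initial_rate <- function(curve, window = c(0, 5),
                         method = c("slope", "endpoint")) {
  stopifnot(inherits(curve, "clearance_curve"))
  method <- match.arg(method)
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("`window` must be an increasing length-2 vector (min)", call. = FALSE)
  }
  inw <- curve$t_min >= window[1] & curve$t_min <= window[2]
  if (sum(inw) < 2) {
    stop("fewer than 2 frames inside the rate window", call. = FALSE)
  }
  t <- curve$t_min[inw]
  pc <- curve$percent_cleared[inw]
  rate <- if (method == "slope") {
    unname(stats::coef(stats::lm(pc ~ t))[2])
  } else {
    (pc[which.max(t)] - pc[which.min(t)]) / (max(t) - min(t))
  }
  structure(list(rate = rate, window = window, n = sum(inw), method = method),
            class = "clearance_rate")
}

#' @export
print.clearance_rate <- function(x, ...) {
  cat(sprintf("Initial clearance rate: %.3g %%/min over %g-%g min (%s, n = %d)\n",
              x$rate, x$window[1], x$window[2], x$method, x$n))
  invisible(x)
}

biphasic_percent <- function(t, f_fast, k_fast, k_slow) {
  100 * (f_fast * (1 - exp(-k_fast * t)) + (1 - f_fast) * (1 - exp(-k_slow * t)))
}

#' Biphasic exponential fit of a clearance curve
#'
#' Airway radiotracer clearance is typically biphasic: a rapid clearance
#' of the majority of particles followed by a slower continuous phase. The
#' standard two-compartment model
#' \deqn{pc(t) = 100 [F (1 - e^{-k_f t}) + (1-F)(1 - e^{-k_s t})]}
#' is fitted by bounded nonlinear least squares (Levenberg-Marquardt) from
#' a grid of starting values; the parameters are returned ordered so that
#' `k_fast >= k_slow`. A fit is flagged degenerate when it collapses to a
#' single exponential (`F` near 0 or 1, or `k_fast` within 5% of
#' `k_slow`).
#'
#' @param curve a [clearance_curve()] with >= 5 points.
#' @return A list of class `biphasic_fit`: `fast_fraction`, `k_fast`,
#'   `k_slow` (1/min), `r_squared`, `degenerate`, `fitted` (function of
#'   t).
#' @export
biphasic_fit <- function(curve) {
  stopifnot(inherits(curve, "clearance_curve"))
  if (nrow(curve) < 5) stop("need >= 5 points for a biphasic fit", call. = FALSE)
  df <- data.frame(t = curve$t_min - curve$t_min[1],
                   pc = curve$percent_cleared)
  span <- max(df$t)
  starts <- expand.grid(f = c(0.3, 0.6, 0.9),
                        kf = c(0.5, 2, 8) / span,
                        ratio = c(0.02, 0.2))
  best <- NULL
  best_sse <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- list(f_fast = starts$f[i], k_fast = starts$kf[i],
               k_slow = starts$kf[i] * starts$ratio[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(pc ~ biphasic_percent(t, f_fast, k_fast, k_slow),
                        data = df, start = st,
                        lower = c(0, 0, 0), upper = c(1, Inf, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("biphasic fit did not converge from any starting point; ",
         "n = ", nrow(df), " points, span ", span, " min", call. = FALSE)
  }
  p <- stats::coef(best)
  f <- unname(p["f_fast"]); kf <- unname(p["k_fast"]); ks <- unname(p["k_slow"])
  if (ks > kf) {  # reorder so the fast compartment is first
    tmp <- kf; kf <- ks; ks <- tmp
    f <- 1 - f
  }
  sst <- sum((df$pc - mean(df$pc))^2)
  r2 <- if (sst > 0) 1 - best_sse / sst else NA_real_
  degenerate <- f < 0.01 || f > 0.99 || kf < 1.05 * ks
  structure(list(fast_fraction = f, k_fast = kf, k_slow = ks,
                 r_squared = r2, degenerate = degenerate,
                 fitted = function(t) biphasic_percent(t, f, kf, ks)),
            class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf(
    "Biphasic clearance fit: F = %.3f, k_fast = %.4g /min, k_slow = %.4g /min, R^2 = %.4f%s\n",
    x$fast_fraction, x$k_fast, x$k_slow, x$r_squared,
    if (x$degenerate) " [degenerate: effectively single-exponential]" else ""))
  invisible(x)
}

#' Clearance rate versus breathing frequency
#'
#' Ordinary least-squares regression of initial clearance rate (%/min) on
#' breathing frequency (breaths per minute), as used to test whether
#' airflow-driven clearance scales with the number of breaths delivered.
#'
#' @param bpm breathing frequencies, breaths/min (n >= 3, non-constant).
#' @param rate initial clearance rates, %/min.
#' @return A list of class `frequency_regression`: `slope`
#'   (%/min per bpm), `intercept` (%/min), `r_squared`, `n`.
#' @export
frequency_regression <- function(bpm, rate) {
  if (length(bpm) != length(rate)) {
    stop("`bpm` and `rate` must have equal length", call. = FALSE)
  }
  if (length(bpm) < 3) stop("need n >= 3 animals", call. = FALSE)
  if (stats::var(bpm) == 0) {
    stop("breathing frequencies are constant; slope is undefined",
         call. = FALSE)
  }
  fit <- stats::lm(rate ~ bpm)
  sst <- sum((rate - mean(rate))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(bpm)),
            class = "frequency_regression")
}

#' @export
print.frequency_regression <- function(x, ...) {
  cat(sprintf(
    "Clearance vs breathing frequency: slope %.4g %%/min/bpm, intercept %.4g %%/min, R^2 = %.3f, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Percent tracheal bead clearance from injected and recovered counts
#'
#' For neonatal bead-clearance assays: particles are deposited in the
#' trachea, the tissue is dissolved after the study, the remaining beads
#' are counted, and clearance is the percentage of injected beads no
#' longer recovered.
#'
#' @param injected number of particles deposited (> 0).
#' @param recovered number of particles recovered (0..injected; values
#'   above `injected` are counting error and are clamped with a warning).
#' @return Percent cleared, `100 * (injected - recovered) / injected`.
#' @export
#' @examples
#' bead_recovery_percent(1000, 400)   # 60
bead_recovery_percent <- function(injected, recovered) {
  if (!is.numeric(injected) || any(injected <= 0)) {
    stop("`injected` must be > 0", call. = FALSE)
  }
  if (any(recovered < 0)) stop("`recovered` must be >= 0", call. = FALSE)
  over <- recovered > injected
  if (any(over)) {
    warning("recovered > injected for ", sum(over),
            " observation(s); clamped to injected")
    recovered <- pmin(recovered, injected)
  }
  100 * (injected - recovered) / injected
}

#' Full clearance analysis pipeline
#'
#' Chains the in vivo analysis steps: coregister frames when fiducials
#' are present, build the percent-cleared curve, compute the initial rate
#' over the chosen window, and fit the biphasic model when enough frames
#' are available.
#'
#' @param frames a `gamma_series`.
#' @param window initial-rate window, minutes. Default `c(0, 5)`.
#' @param decay_correct,background passed to [clearance_curve()].
#' @return A list of class `glt_clearance_analysis`: `frames`
#'   (registered), `curve`, `rate`, `fit` (or `NULL` when < 5 frames).
#' @export
analyze_clearance <- function(frames, window = c(0, 5),
                              decay_correct = FALSE, background = 0) {
  stopifnot(inherits(frames, "gamma_series"))
  has_fid <- any(grepl("^fid[0-9]+_x$", names(frames)))
  if (has_fid) frames <- register_frames(frames)
  curve <- clearance_curve(frames, decay_correct = decay_correct,
                           background = background)
  rate <- initial_rate(curve, window = window)
  fit <- if (nrow(curve) >= 5) biphasic_fit(curve) else NULL
  structure(list(frames = frames, curve = curve, rate = rate, fit = fit),
            class = "glt_clearance_analysis")
}

#' @export
print.glt_clearance_analysis <- function(x, ...) {
  print(x$curve)
  print(x$rate)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
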