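#' Airflow pulse protocol
#'
#' Timing and direction of a breath-mimicking unidirectional airflow pulse
#' applied to an airway culture: a no-flow (pre-pulse) phase used to
#' estimate baseline ciliary drift, the air pulse itself, and a recovery
#' phase in which the viscoelastic mucus layer recoils. The default is the
#' 15 s protocol used throughout: 5 s no flow, 5 s pulse, 5 s recovery.
#'
#' @param t_pre_start start of the recording / no-flow phase, s.
#' @param t_pulse_start airflow pulse onset, s.
#' @param t_pulse_end airflow pulse offset, s.
#' @param t_end end of the recovery phase (end of recording), s.
#' @param axis unit 2-vector giving the airflow direction in the image
#'   plane; normalized if not already unit length.
#' @param pulse_velocity airflow velocity during the pulse, m/s (1 mimics
#'   resting expiratory velocities in proximal generations, 5 exercise).
#' @return A list of class `pulse_protocol`.
#' @export
#' @examples
#' pulse_protocol()                          # 0/5/10/15 s, 5 m/s along +x
#' pulse_protocol(t_pulse_end = 7.5, pulse_velocity = 1)
pulse_protocol <- function(t_pre_start = 0, t_pulse_start = 5,
                           t_pulse_end = 10, t_end = 15,
                           axis = c(1, 0), pulse_velocity = 5) {
  if (!(t_pre_start < t_pulse_start && t_pulse_start < t_pulse_end &&
        t_pulse_end <= t_end)) {
    stop("protocol times must satisfy t_pre_start < t_pulse_start < ",
         "t_pulse_end <= t_end", call. = FALSE)
  }
  if (length(axis) != 2 || any(!is.finite(axis)) || all(axis == 0)) {
    stop("`axis` must be a finite non-zero 2-vector", call. = FALSE)
  }
  if (!is.numeric(pulse_velocity) || pulse_velocity < 0) {
    stop("`pulse_velocity` must be non-negative (m/s)", call. = FALSE)
  }
  axis <- axis / sqrt(sum(axis^2))
  structure(
    list(t_pre_start = t_pre_start, t_pulse_start = t_pulse_start,
         t_pulse_end = t_pulse_end, t_end = t_end,
         axis = axis, pulse_velocity = pulse_velocity),
    class = "pulse_protocol"
  )
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf(
    "Airflow pulse protocol: pre %g-%g s | pulse %g-%g s (%g m/s) | recovery to %g s\n",
    x$t_pre_start, x$t_pulse_start, x$t_pulse_start, x$t_pulse_end,
    x$pulse_velocity, x$t_end))
  cat(sprintf("  airflow axis: (%.3f, %.3f)\n", x$axis[1], x$axis[2]))
  invisible(x)
}

#' Read a pulse protocol from a JSON file
#'
#' Expects a JSON object with any of the fields of [pulse_protocol()];
#' missing fields take the defaults.
#'
#' @param path JSON file path.
#' @return A `pulse_protocol`.
#' @export
read_protocol <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pulse_protocol))
  unknown <- setdiff(names(spec), known)
  if (length(unknown) > 0) {
    stop("unknown protocol field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pulse_protocol, spec)
}
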