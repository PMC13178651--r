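# Build a small noiseless track table by explicit position formulas,
# independent of the simulator, for forced-value tests.
make_track <- function(id, t, x, y, frame_rate = 100) {
  glt_tracks(track_id = rep(id, length(t)), frame = round(t * frame_rate),
             x = x, y = y, frame_rate = frame_rate)
}

bind_tracks <- function(...) {
  pieces <- list(...)
  fr <- attr(pieces[[1]], "frame_rate")
  df <- do.call(rbind, lapply(pieces, as.data.frame))
  out <- glt_tracks(df$track_id, df$frame, df$x, df$y, frame_rate = fr,
                    t = df$t)
  out
}

# A bead that sits still, jumps +20 um along +x during the 5-10 s pulse
# (linearly), then recoils -5 um during recovery. Sampled at 10 fps to
# keep fixtures small.
piecewise_bead <- function(id = "b1", frame_rate = 10) {
  t <- seq(0, 15, by = 1 / frame_rate)
  x <- ifelse(t <= 5, 0,
       ifelse(t <= 10, (t - 5) / 5 * 20,
              20 - (t - 10) / 5 * 5))
  make_track(id, t, x = x, y = rep(0, length(t)), frame_rate = frame_rate)
}

default_protocol <- function(...) pulse_protocol(...)
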