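#' Construct a sensor_epochs container
#'
#' @param alignment `"stimulus"` or `"response"` (t = 0 at stimulus onset or
#'   at the button press).
#' @param values Numeric array, trial x sensor x time.
#' @param times_ms Strictly increasing time grid with constant step
#'   `1000 / sampling_rate_hz`.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param trial_ids Trial ids linking rows of `values` to a `trial_table`.
#' @return A `sensor_epochs` object.
#' @export
sensor_epochs <- function(alignment, values, times_ms, sampling_rate_hz,
                          trial_ids) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[3] == length(times_ms),
            dim(values)[1] == length(trial_ids))
  step <- 1000 / sampling_rate_hz
  d <- diff(times_ms)
  if (any(d <= 0) || any(abs(d - step) > 1e-6))
    stop("times_ms must be strictly increasing with step 1000/sampling_rate_hz")
  structure(list(alignment = match.arg(alignment, c("stimulus", "response")),
                 times_ms = times_ms, sampling_rate_hz = sampling_rate_hz,
                 values = values, trial_ids = trial_ids),
            class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  cat(sprintf("Sensor epochs (%s-aligned): %d trials x %d sensors x %d samples, %g-%g ms @ %g Hz\n",
              x$alignment, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$times_ms), max(x$times_ms), x$sampling_rate_hz))
  invisible(x)
}

# Feature level of each trial for one information type.
trial_levels <- function(trials, info_type) {
  switch(info_type,
         across = trials$hemifield,
         within = trials$eccentricity,
         rule = as.character(trials$rule),
         response = trials$response_group,
         stop("unknown info_type: ", info_type))
}

# Raised-cosine on/off envelope: 1 inside [w0, w1] with smooth ramps of
# `ramp` ms at the edges, 0 outside. NULL window = always on.
effect_envelope <- function(t, window_ms, ramp = 20) {
  if (is.null(window_ms)) return(rep(1, length(t)))
  w0 <- window_ms[1]; w1 <- window_ms[2]
  ramp <- min(ramp, (w1 - w0) / 2)
  e <- numeric(length(t))
  inside <- t >= w0 & t <= w1
  e[inside] <- 1
  if (ramp > 0) {
    up <- t >= w0 & t < w0 + ramp
    dn <- t > w1 - ramp & t <= w1
    e[up] <- 0.5 * (1 - cos(pi * (t[up] - w0) / ramp))
    e[dn] <- 0.5 * (1 - cos(pi * (w1 - t[dn]) / ramp))
  }
  e
}

#' Simulate MEG sensor epochs with window-limited condition effects
#'
#' Every level of a planted information type has a fixed latent sensor
#' topography; the topography is added to i.i.d. Gaussian sensor noise only
#' inside the effect's time window, scaled by a raised-cosine on/off envelope
#' (20 ms ramps) and the effect size (in noise-SD units). Response-aligned
#' epochs place t = 0 at the button press, i.e. each trial's signal is
#' shifted by its reaction time. With `alignment = "both"`, the two epoch
#' frames are cut from one shared per-trial time series, so a response-aligned
#' sample at time -RT equals the stimulus-aligned sample at time 0 (up to
#' linear interpolation when RT is off-grid). Omitted trials (no response
#' time) are dropped.
#'
#' @param trials A `trial_table`.
#' @param n_sensors Number of sensors (default 160).
#' @param effect_specs List of [effect_spec()] objects with `window_ms`.
#' @param alignment `"stimulus"`, `"response"` or `"both"`.
#' @param sampling_rate_hz Sampling rate (default 200).
#' @param span_stim_ms Stimulus-aligned epoch span (default -200..2500 ms).
#' @param span_resp_ms Response-aligned epoch span (default -2500..500 ms).
#' @param noise_sd Sensor noise SD.
#' @param seed Integer seed.
#' @return A `sensor_epochs` object, or for `alignment = "both"` a named list
#'   with elements `stimulus` and `response`.
#' @export
simulate_meg_epochs <- function(trials, n_sensors = 160L, effect_specs = list(),
                                alignment = c("stimulus", "response", "both"),
                                sampling_rate_hz = 200,
                                span_stim_ms = c(-200, 2500),
                                span_resp_ms = c(-2500, 500),
                                noise_sd = 1, seed = NULL) {
  alignment <- match.arg(alignment)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (inherits(effect_specs, "effect_spec")) effect_specs <- list(effect_specs)
  step <- 1000 / sampling_rate_hz
  for (es in effect_specs) {
    if (is.null(es$window_ms)) next
    span <- if (es$frame == "stimulus") span_stim_ms else span_resp_ms
    check <- (es$frame == "stimulus" && alignment != "response") ||
      (es$frame == "response" && alignment != "stimulus")
    if (check && (es$window_ms[1] < span[1] || es$window_ms[2] > span[2]))
      stop("effect window ", es$window_ms[1], "..", es$window_ms[2],
           " ms lies outside the ", es$frame, "-aligned epoch span")
  }
  if (!is.null(seed)) set.seed(seed)
  tr <- trials[!trials$omitted, , drop = FALSE]
  n <- nrow(tr)
  rt <- tr$rt_ms

  # latent topographies first, in effect order, so they are seed-stable
  topos <- lapply(effect_specs, function(es) {
    lev <- trial_levels(tr, es$info_type)
    latent_level_patterns(lev, n_sensors)
  })
  levs <- lapply(effect_specs, function(es) trial_levels(tr, es$info_type))

  # expected signal for one trial at stimulus-frame times t
  trial_signal <- function(i, t_stim) {
    sig <- matrix(0, n_sensors, length(t_stim))
    for (k in seq_along(effect_specs)) {
      es <- effect_specs[[k]]
      li <- levs[[k]][i]
      if (is.na(li) || !li %in% rownames(topos[[k]])) next
      t_frame <- if (es$frame == "stimulus") t_stim else t_stim - rt[i]
      env <- effect_envelope(t_frame, es$window_ms)
      if (any(env > 0))
        sig <- sig + es$effect_size * outer(topos[[k]][li, ], env)
    }
    sig
  }

  make_epochs <- function(times, stim_time_of) {
    vals <- array(NA_real_, c(n, n_sensors, length(times)))
    for (i in seq_len(n)) {
      ts <- stim_time_of(i, times)
      vals[i, , ] <- matrix(stats::rnorm(n_sensors * length(times), sd = noise_sd),
                            n_sensors) + trial_signal(i, ts)
    }
    vals
  }

  t_stim <- seq(span_stim_ms[1], span_stim_ms[2], by = step)
  t_resp <- seq(span_resp_ms[1], span_resp_ms[2], by = step)

  if (alignment == "stimulus") {
    vals <- make_epochs(t_stim, function(i, tt) tt)
    return(sensor_epochs("stimulus", vals, t_stim, sampling_rate_hz, tr$trial_id))
  }
  if (alignment == "response") {
    vals <- make_epochs(t_resp, function(i, tt) tt + rt[i])
    return(sensor_epochs("response", vals, t_resp, sampling_rate_hz, tr$trial_id))
  }

  # both: cut the two frames out of one shared per-trial master series
  vs <- array(NA_real_, c(n, n_sensors, length(t_stim)))
  vr <- array(NA_real_, c(n, n_sensors, length(t_resp)))
  for (i in seq_len(n)) {
    m0 <- floor(min(span_stim_ms[1], rt[i] + span_resp_ms[1]) / step) * step
    m1 <- ceiling(max(span_stim_ms[2], rt[i] + span_resp_ms[2]) / step) * step
    mt <- seq(m0, m1, by = step)
    M <- matrix(stats::rnorm(n_sensors * length(mt), sd = noise_sd), n_sensors) +
      trial_signal(i, mt)
    idx_s <- round((t_stim - m0) / step) + 1L
    vs[i, , ] <- M[, idx_s]
    pos <- (rt[i] + t_resp - m0) / step
    lo <- pmin(floor(pos), length(mt) - 2L)
    w <- pos - lo
    vr[i, , ] <- M[, lo + 1L] * rep(1 - w, each = n_sensors) +
      M[, lo + 2L] * rep(w, each = n_sensors)
  }
  list(stimulus = sensor_epochs("stimulus", vs, t_stim, sampling_rate_hz, tr$trial_id),
       response = sensor_epochs("response", vr, t_resp, sampling_rate_hz, tr$trial_id))
}
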