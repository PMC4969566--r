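# Synthetic voltage segments with analytic ground truth. These emulate the
# study conditions of the polysomnogram recordings — 250 Hz, one-minute
# single-channel segments grouped by subject and state — while providing
# signals whose expected kappa statistics are known in closed form:
#
#   * ramp:              V(t) = slope * t           -> kappa = 1 exactly
#   * alternating:       0, a, 0, a, ...            -> kappa = ln(a)/ln(dt)
#   * white_noise:       iid N(0, sigma^2)
#   * fbm:               fractional Brownian motion, Var[dV] = sigma^2 dt^(2H)
#   * sinusoid_mix:      sum of sinusoids
#   * powerlaw_increment: |V(t+lag) - V(t)| = c * dt^k0 exactly at one lag
#
# fBm is synthesized by circulant embedding (Davies-Harte), which gives the
# exact increment covariance, so the fBm law E[kappa] = H +
# (ln sigma + E ln|Z|) / ln(dt) is a sharp test rather than an asymptotic
# one. Amplitudes default to mV-like magnitudes (order 1e-2 to 1e0) so that
# kappa changes sign between sub-second and multi-second intervals.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Specification of one synthetic voltage segment
#'
#' @param kind One of `"ramp"`, `"alternating"`, `"white_noise"`, `"fbm"`,
#'   `"sinusoid_mix"`, `"powerlaw_increment"`.
#' @param fs Sampling rate in Hz (default 250, the study rate).
#' @param duration_s Segment length in seconds (default 60, one-minute
#'   tracings).
#' @param seed Integer seed; the generated samples are a deterministic
#'   function of the spec including the seed.
#' @param ... Kind-specific parameters:
#'   * ramp: `slope` (voltage units per second, default 1)
#'   * alternating: `amplitude` (default 2; samples alternate 0, amplitude)
#'   * white_noise: `sigma` (default 1)
#'   * fbm: `hurst` in (0, 1), `sigma` (increment scale so that
#'     `Var[V(t+dt) - V(t)] = sigma^2 * dt^(2*hurst)`, dt in seconds;
#'     defaults 0.5 and 1)
#'   * sinusoid_mix: `freqs` (Hz), `amps`, optional `phases`
#'   * powerlaw_increment: `kappa0`, `c` (increment magnitude
#'     `c * dt^kappa0`), `lag_delta_t_s` (the interval, in seconds, at
#'     which the increment magnitude is exact; default 0.004)
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(kind, fs = 250, duration_s = 60, seed = 1L, ...) {
  kinds <- c("ramp", "alternating", "white_noise", "fbm", "sinusoid_mix",
             "powerlaw_increment")
  if (!kind %in% kinds)
    stop_param("unknown synthetic kind '%s' (expected one of %s)", kind,
               paste(kinds, collapse = ", "))
  if (duration_s * fs < 2)
    stop_param("duration_s * fs must be >= 2")
  params <- list(...)
  if (kind == "fbm") {
    h <- params$hurst %||% 0.5
    if (h <= 0 || h >= 1) stop_param("hurst must lie in (0, 1), got %g", h)
    if ((params$sigma %||% 1) <= 0) stop_param("sigma must be positive")
  }
  structure(list(kind = kind, fs = fs, duration_s = duration_s,
                 seed = seed, params = params),
            class = "synth_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact fractional Gaussian noise by circulant embedding
#'
#' Davies-Harte synthesis: the fGn autocovariance is embedded in a
#' circulant matrix whose eigenvalues (a real FFT) are all nonnegative for
#' Hurst exponents in (0, 1), so the returned sample has exactly the target
#' covariance, not an approximation.
#'
#' @param n Number of increments.
#' @param hurst Hurst exponent in (0, 1).
#' @param sd_increment Standard deviation of one increment.
#' @return Numeric vector of `n` stationary Gaussian increments.
#' @keywords internal
fgn_davies_harte <- function(n, hurst, sd_increment = 1) {
  h2 <- 2 * hurst
  # embed in a power-of-two circulant (>= 2n) so the FFT length never hits
  # a large prime factor
  m <- stats::nextn(2L * n, 2L)
  half <- m %/% 2L
  k <- 0:half
  gamma <- sd_increment^2 / 2 *
    (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  circ <- c(gamma, rev(gamma[2:half]))
  lambda <- Re(stats::fft(circ))
  if (min(lambda) < -1e-8 * max(lambda))
    stop_param("circulant embedding not nonnegative definite (H=%g)", hurst)
  lambda[lambda < 0] <- 0
  w <- complex(length.out = m)
  z <- stats::rnorm(2L)
  w[1L] <- sqrt(lambda[1L] / m) * z[1L]
  w[half + 1L] <- sqrt(lambda[half + 1L] / m) * z[2L]
  j <- 2:half
  u <- stats::rnorm(half - 1L); v <- stats::rnorm(half - 1L)
  w[j] <- sqrt(lambda[j] / (2 * m)) * complex(real = u, imaginary = v)
  w[m + 2L - j] <- Conj(w[j])
  Re(stats::fft(w))[1:n]
}

#' Generate a synthetic voltage segment
#'
#' @param spec A [synth_spec()].
#' @param subject_id,state,segment_id,units Metadata for the returned
#'   segment.
#' @return A [voltage_segment()]; bit-identical for identical specs.
#' @examples
#' seg <- generate_segment(synth_spec("fbm", hurst = 0.5, sigma = 1, seed = 7))
#' round(estimate_hurst(seg), 2)
#' @export
generate_segment <- function(spec, subject_id = "s01", state = "synthetic",
                             segment_id = "seg001", units = "mV") {
  stopifnot(inherits(spec, "synth_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs))
  p <- spec$params
  tt <- (0:(n - 1L)) / spec$fs
  samples <- with_seed(spec$seed, switch(
    spec$kind,
    ramp = (p$slope %||% 1) * tt,
    alternating = rep(c(0, p$amplitude %||% 2), length.out = n),
    white_noise = stats::rnorm(n, sd = p$sigma %||% 1),
    fbm = {
      h <- p$hurst %||% 0.5
      sigma <- p$sigma %||% 1
      inc <- fgn_davies_harte(n - 1L, h, sd_increment = sigma / spec$fs^h)
      cumsum(c(0, inc))
    },
    sinusoid_mix = {
      freqs <- p$freqs %||% c(1, 10)
      amps <- p$amps %||% rep(1, length(freqs))
      phases <- p$phases %||% stats::runif(length(freqs), 0, 2 * pi)
      Reduce(`+`, Map(function(f, a, ph) a * sin(2 * pi * f * tt + ph),
                      freqs, amps, phases))
    },
    powerlaw_increment = {
      dt <- p$lag_delta_t_s %||% 0.004
      lag <- as.integer(round(dt * spec$fs))
      if (lag < 1L || lag >= n)
        stop_param("powerlaw_increment lag %d invalid for n=%d", lag, n)
      a <- (p$c %||% 1) * dt^(p$kappa0 %||% 0.5)
      v <- numeric(n)
      signs <- sample(c(-1, 1), n - lag, replace = TRUE)
      for (t in seq_len(n - lag))
        v[t + lag] <- v[t] + signs[t] * a
      v
    }))
  voltage_segment(samples, fs = spec$fs, units = units,
                  subject_id = subject_id, state = state,
                  segment_id = segment_id)
}

#' Specification of a multi-subject synthetic cohort
#'
#' Each state is described by a [synth_spec()] template; each subject draws
#' one Gaussian offset on a chosen template parameter (shared across that
#' subject's states, emulating stable individual differences) and then
#' generates `segments_per_state` independent segments per state.
#'
#' @param n_subjects Number of subjects (>= 2; the study used 14 with 11
#'   overlapping for deep sleep).
#' @param segments_per_state One-minute segments per subject and state
#'   (default 8, as in the study design).
#' @param states Named list of `synth_spec` templates, one per state label.
#' @param subject_effect_param Template parameter receiving the
#'   between-subject offset (`"hurst"` or `"sigma"`; default `"hurst"`).
#' @param subject_effect_sd SD of the Gaussian subject offset (default
#'   0.03; Hurst offsets are clipped to (0.05, 0.95)).
#' @param seed Integer master seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects, segments_per_state = 8L, states,
                        subject_effect_param = "hurst",
                        subject_effect_sd = 0.03, seed = 1L) {
  if (n_subjects < 2L) stop_param("n_subjects must be >= 2")
  if (segments_per_state < 1L) stop_param("segments_per_state must be >= 1")
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop_param("states must be a named list of synth_spec templates")
  for (s in states) stopifnot(inherits(s, "synth_spec"))
  structure(list(n_subjects = as.integer(n_subjects),
                 segments_per_state = as.integer(segments_per_state),
                 states = states,
                 subject_effect_param = subject_effect_param,
                 subject_effect_sd = subject_effect_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic multi-subject cohort
#'
#' Produces, per subject and state, one recording made of
#' `segments_per_state` independently generated one-epoch stretches (joined
#' continuously so epoch boundaries carry no jumps), the matching
#' whole-recording [stage_annotation()], the already-split epoch segments,
#' and a truth table recording every realized parameter.
#'
#' @param cs A [cohort_spec()].
#' @return A list with elements `segments` (list of [voltage_segment()]),
#'   `recordings` (list of per subject-state recordings), `annotations`
#'   (matching [stage_annotation()]s), and `truth` (data.frame of realized
#'   parameters per subject, state and segment).
#' @export
generate_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  offsets <- with_seed(cs$seed,
                       stats::rnorm(cs$n_subjects, 0, cs$subject_effect_sd))
  clipped <- 0L
  segments <- list()
  recordings <- list()
  annotations <- list()
  truth <- list()
  seg_seed <- function(i, s, k)  # distinct sub-seed per segment, < 2^31
    (cs$seed * 7919L + i * 104729L + s * 1299709L + k * 15485863L) %%
      2147483629L
  state_names <- names(cs$states)
  for (i in seq_len(cs$n_subjects)) {
    sid <- sprintf("s%02d", i)
    for (s in seq_along(cs$states)) {
      template <- cs$states[[s]]
      p <- template$params
      if (cs$subject_effect_param == "hurst" && !is.null(p$hurst)) {
        h <- p$hurst + offsets[i]
        hc <- min(max(h, 0.05), 0.95)
        if (hc != h) clipped <- clipped + 1L
        p$hurst <- hc
      } else if (cs$subject_effect_param == "sigma" && !is.null(p$sigma)) {
        p$sigma <- max(p$sigma * exp(offsets[i]), 1e-12)
      }
      segs <- vector("list", cs$segments_per_state)
      for (k in seq_len(cs$segments_per_state)) {
        sp <- synth_spec(template$kind, fs = template$fs,
                         duration_s = template$duration_s,
                         seed = seg_seed(i, s, k))
        sp$params <- p
        seg <- generate_segment(sp, subject_id = sid,
                                state = state_names[s],
                                segment_id = sprintf("seg%03d", k))
        segs[[k]] <- seg
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = sid, state = state_names[s],
          segment_id = seg$segment_id, kind = template$kind,
          hurst = p$hurst %||% NA_real_, sigma = p$sigma %||% NA_real_,
          seed = sp$seed, stringsAsFactors = FALSE)
      }
      # join epochs continuously: offset each epoch to start where the
      # previous one ended, so within-epoch increments are untouched
      joined <- segs[[1L]]$samples
      for (k in seq_len(cs$segments_per_state)[-1L]) {
        x <- segs[[k]]$samples
        joined <- c(joined, x - x[1L] + joined[length(joined)])
      }
      rec <- voltage_segment(joined, fs = template$fs,
                             subject_id = sid, state = state_names[s],
                             segment_id = sprintf("%s_%s", sid,
                                                  state_names[s]))
      recordings[[rec$segment_id]] <- rec
      annotations[[rec$segment_id]] <- stage_annotation(
        0, cs$segments_per_state * template$duration_s, state_names[s])
      segments <- c(segments, segs)
    }
  }
  if (clipped > 0.1 * cs$n_subjects * length(cs$states))
    warning("subject-effect clipping affected more than 10% of ",
            "subject-state cells (", clipped, ")")
  list(segments = segments, recordings = recordings,
       annotations = annotations, truth = do.call(rbind, truth))
}
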