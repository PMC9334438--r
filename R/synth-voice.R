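#' Specify a synthetic voice
#'
#' A \code{voice_spec} fixes every ground-truth parameter of one synthesized
#' sentence: the fundamental-frequency contour (linear in period from
#' \code{f0_start_hz} to \code{f0_end_hz}), cycle-to-cycle jitter, the first
#' five formant resonances with their bandwidths, and the level of additive
#' broadband noise relative to the harmonic source.
#'
#' @param duration_s Sentence duration in seconds (> 0).
#' @param f0_start_hz,f0_end_hz Fundamental frequency at sentence start and
#'   end, Hz. The glottal period is interpolated linearly between
#'   \code{1/f0_start_hz} and \code{1/f0_end_hz}.
#' @param jitter_frac Multiplicative cycle-to-cycle period perturbation,
#'   dimensionless, in \code{[0, 0.2)}. Each period is scaled by
#'   \code{1 + jitter_frac * u} with \code{u} i.i.d. uniform on (-1, 1).
#' @param formants_hz Five strictly ascending formant center frequencies, Hz.
#' @param bandwidths_hz Five formant bandwidths, Hz.
#' @param noise_db Level of additive white noise relative to the harmonic
#'   component, dB (power). \code{-Inf} disables noise.
#' @param sample_rate_hz Sampling rate, Hz. All frequencies must lie below
#'   the Nyquist frequency.
#' @return An object of class \code{"voice_spec"}.
#' @examples
#' sp <- voice_spec(1, 180, 180)
#' w <- synthesize_voice(sp, seed = 1)
#' @export
voice_spec <- function(duration_s,
                       f0_start_hz,
                       f0_end_hz = f0_start_hz,
                       jitter_frac = 0,
                       formants_hz = c(500, 1500, 2500, 3500, 4500),
                       bandwidths_hz = c(80, 120, 160, 220, 280),
                       noise_db = -40,
                       sample_rate_hz = 44100) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz < 12000) {
    stop_field("sample_rate_hz", "must be at least 12000 Hz (6 kHz band edge)")
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1 || !is.finite(duration_s) ||
      duration_s <= 0) {
    stop_field("duration_s", "must be a single positive number")
  }
  nyq <- sample_rate_hz / 2
  for (f in c("f0_start_hz", "f0_end_hz")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v >= nyq) {
      stop_field(f, "must be a positive frequency below Nyquist")
    }
  }
  if (!is.numeric(jitter_frac) || length(jitter_frac) != 1 ||
      jitter_frac < 0 || jitter_frac >= 0.2) {
    stop_field("jitter_frac", "must lie in [0, 0.2)")
  }
  if (length(formants_hz) != 5 || any(diff(formants_hz) <= 0)) {
    stop_field("formants_hz", "must be 5 strictly ascending frequencies")
  }
  if (any(formants_hz >= nyq)) {
    stop_field("formants_hz", "must all lie below Nyquist")
  }
  if (length(bandwidths_hz) != 5 || any(bandwidths_hz <= 0)) {
    stop_field("bandwidths_hz", "must be 5 positive bandwidths")
  }
  if (!is.numeric(noise_db) || length(noise_db) != 1 || is.na(noise_db)) {
    stop_field("noise_db", "must be a single number (possibly -Inf)")
  }
  structure(
    list(
      duration_s = duration_s,
      f0_start_hz = f0_start_hz,
      f0_end_hz = f0_end_hz,
      jitter_frac = jitter_frac,
      formants_hz = as.numeric(formants_hz),
      bandwidths_hz = as.numeric(bandwidths_hz),
      noise_db = noise_db,
      sample_rate_hz = sample_rate_hz
    ),
    class = "voice_spec"
  )
}

#' Ground-truth fundamental-frequency contour of a voice spec
#'
#' @param spec A \code{\link{voice_spec}}.
#' @param t Times in seconds.
#' @return Instantaneous f0 (Hz) at \code{t}: the reciprocal of the linearly
#'   interpolated glottal period.
#' @export
voice_contour <- function(spec, t) {
  T0 <- 1 / spec$f0_start_hz
  T1 <- 1 / spec$f0_end_hz
  frac <- pmin(pmax(t / spec$duration_s, 0), 1)
  1 / (T0 + (T1 - T0) * frac)
}

#' Construct a waveform object
#'
#' @param samples Numeric amplitude sequence in \code{[-1, 1]}.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return An object of class \code{"waveform"}.
#' @export
waveform <- function(samples, sample_rate_hz) {
  if (any(!is.finite(samples))) stop_field("samples", "must be finite")
  structure(
    list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d samples, %.3f s @ %d Hz>\n",
    length(x$samples), length(x$samples) / x$sample_rate_hz,
    as.integer(x$sample_rate_hz)
  ))
  invisible(x)
}

# Second-order resonator (digital formant) applied in cascade.
# Pole radius r = exp(-pi * bw / fs), angle 2*pi*f / fs; unity gain at DC
# is not enforced -- overall level is normalized after the cascade.
resonate <- function(x, f_hz, bw_hz, fs) {
  r <- exp(-pi * bw_hz / fs)
  theta <- 2 * pi * f_hz / fs
  a1 <- 2 * r * cos(theta)
  a2 <- -r^2
  gain <- 1 - 2 * r * cos(theta) + r^2
  as.numeric(stats::filter(gain * x, c(a1, a2), method = "recursive"))
}

#' Synthesize a speech-like sentence from a voice spec
#'
#' Source-filter synthesis with analytically known ground truth: the glottal
#' source is a pulse train whose period follows the spec's linear contour,
#' each period multiplicatively perturbed by \code{jitter_frac}; the source is
#' shaped by a first-order low-pass (glottal spectral tilt) and filtered
#' through five second-order resonators at the spec's formants; white noise is
#' mixed in at \code{noise_db} relative to the harmonic component. The result
#' is peak-normalized to 0.9. Identical \code{(spec, seed)} give bit-identical
#' samples; the global RNG state is left untouched.
#'
#' @param spec A valid \code{\link{voice_spec}}.
#' @param seed Integer seed controlling jitter and noise.
#' @return A \code{\link{waveform}} with attributes \code{"spec"} and
#'   \code{"pulse_times"} (the exact glottal epochs, seconds) preserved as
#'   synthesis ground truth.
#' @export
synthesize_voice <- function(spec, seed = 1L) {
  if (!inherits(spec, "voice_spec")) {
    spec <- do.call(voice_spec, unclass(spec))
  }
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  with_seed(seed, {
    # glottal epochs: t_{k+1} = t_k + T(t_k) * (1 + j * u_k)
    T0 <- 1 / spec$f0_start_hz
    T1 <- 1 / spec$f0_end_hz
    tmax <- spec$duration_s
    times <- numeric(ceiling(tmax * max(spec$f0_start_hz, spec$f0_end_hz)) + 16)
    k <- 0L
    t <- 0
    while (t < tmax) {
      k <- k + 1L
      if (k > length(times)) times <- c(times, numeric(64))
      times[k] <- t
      Tt <- T0 + (T1 - T0) * (t / tmax)
      if (spec$jitter_frac > 0) {
        Tt <- Tt * (1 + spec$jitter_frac * stats::runif(1, -1, 1))
      }
      t <- t + Tt
    }
    pulse_times <- times[seq_len(k)]

    # band-limited pulse placement: a windowed sinc at the exact fractional
    # sample position (plain rounding adds ~0.3-sample timing noise, which
    # caps the achievable harmonics-to-noise ratio near 25 dB)
    src <- numeric(n + 32L)
    half <- 8L
    for (tp in pulse_times) {
      pos <- tp * fs + 1
      n0 <- floor(pos)
      frac <- pos - n0
      j <- (-half):half
      arg <- j - frac
      s <- ifelse(abs(arg) < 1e-12, 1, sin(pi * arg) / (pi * arg))
      s <- s * (0.5 + 0.5 * cos(pi * arg / (half + 1)))  # Hann taper
      at <- n0 + j + half
      ok <- at >= 1L & at <= length(src)
      src[at[ok]] <- src[at[ok]] + s[ok]
    }
    src <- src[(half + 1L):(half + n)]

    # glottal tilt: one-pole low-pass (~ -6 dB/oct above ~2 kHz)
    src <- as.numeric(stats::filter(src, 0.7, method = "recursive"))

    harm <- src
    for (i in 1:5) {
      harm <- resonate(harm, spec$formants_hz[i], spec$bandwidths_hz[i], fs)
    }
    # higher-pole correction (Klatt): two wide fixed resonators above the
    # formant range stand in for the vocal tract's F6, F7, ...; without them
    # a truncated 5-pole cascade buries F5 under the lower formants' skirts
    harm <- resonate(harm, 6500, 600, fs)
    harm <- resonate(harm, 9000, 1000, fs)

    if (is.finite(spec$noise_db)) {
      noise <- stats::rnorm(n)
      target_rms <- sqrt(mean(harm^2)) * 10^(spec$noise_db / 20)
      noise <- noise * target_rms / sqrt(mean(noise^2))
      x <- harm + noise
    } else {
      x <- harm
    }
    x <- 0.9 * x / max(abs(x))
    w <- waveform(x, fs)
    attr(w, "spec") <- spec
    attr(w, "pulse_times") <- pulse_times
    w
  })
}

#' Jitter of a pulse sequence, directly from epoch times
#'
#' Local (period-to-period) jitter computed straight from glottal epochs:
#' mean absolute difference between consecutive periods divided by the mean
#' period. Used both on synthesis ground truth and on extracted pulses.
#'
#' @param pulse_times Strictly increasing epoch times, seconds.
#' @return Dimensionless local jitter, or \code{NA} with fewer than 3 pulses.
#' @export
pulse_jitter <- function(pulse_times) {
  if (length(pulse_times) < 3) return(NA_real_)
  per <- diff(pulse_times)
  mean(abs(diff(per))) / mean(per)
}

#' Default speaker profiles for the synthetic corpus
#'
#' Draws per-speaker parameter means emulating a stimulus set of one owner
#' plus unfamiliar control persons, half of them male. Female speakers centre
#' around a 200 Hz mean f0 and male speakers around 120 Hz, the naturally
#' gender-discriminating f0 gap. Speakers further differ in jitter, overall
#' vocal-tract (formant) scale, and noisiness. Within-speaker
#' sentence-to-sentence standard deviations are set to
#' \code{within_frac} of the corresponding between-speaker spread, so
#' sentence variation stays smaller than speaker separation.
#'
#' @param n_speakers Number of speakers (owner + controls; default 15).
#' @param seed Integer seed for the profile draws.
#' @param within_frac Within-speaker SD as a fraction of the between-speaker
#'   SD for every parameter (default 0.25).
#' @return A data frame of class \code{"speaker_profiles"}, one row per
#'   speaker, with per-parameter means and within-speaker SDs.
#' @export
speaker_profiles <- function(n_speakers = 15, seed = 100L, within_frac = 0.25) {
  if (n_speakers < 2) stop("need at least 2 speakers", call. = FALSE)
  gender <- rep(c("female", "male"), length.out = n_speakers)
  # between-speaker SDs, per gender where relevant
  f0_between <- ifelse(gender == "female", 20, 15)
  jit_between <- 0.008
  scale_between <- 0.04
  noise_between <- 4
  with_seed(seed, {
    f0_mu <- ifelse(gender == "female", 200, 120) +
      stats::rnorm(n_speakers, 0, f0_between)
    jit_mu <- pmax(0.004, 0.018 + stats::rnorm(n_speakers, 0, jit_between))
    scale_mu <- 1 + stats::rnorm(n_speakers, 0, scale_between)
    noise_mu <- -30 + stats::rnorm(n_speakers, 0, noise_between)
  })
  base_formants <- ifelse(gender == "female", 1.08, 1.0)
  out <- data.frame(
    speaker_id = sprintf("S%02d", seq_len(n_speakers)),
    gender = gender,
    f0_mean = f0_mu,
    f0_sd = within_frac * f0_between,
    jitter_mean = jit_mu,
    jitter_sd = within_frac * jit_between,
    formant_scale = scale_mu * base_formants,
    formant_scale_sd = within_frac * scale_between,
    noise_db_mean = noise_mu,
    noise_db_sd = within_frac * noise_between,
    duration_mean = 2.0,
    duration_sd = 0.15,
    slope_sd = 0.04,
    stringsAsFactors = FALSE
  )
  class(out) <- c("speaker_profiles", "data.frame")
  out
}

#' Draw one sentence spec from a speaker profile
#'
#' @param profile One row of a \code{\link{speaker_profiles}} table.
#' @param sample_rate_hz Sampling rate for the sentence.
#' @return A \code{\link{voice_spec}}. Uses the current RNG stream.
#' @keywords internal
draw_sentence_spec <- function(profile, sample_rate_hz = 44100) {
  level <- stats::rnorm(1, profile$f0_mean, profile$f0_sd)
  level <- max(level, 60)
  slope <- stats::rnorm(1, 0, profile$slope_sd)
  fsc <- stats::rnorm(1, profile$formant_scale, profile$formant_scale_sd)
  fsc <- max(fsc, 0.7)
  base <- c(500, 1500, 2500, 3500, 4500)
  voice_spec(
    duration_s = max(0.8, stats::rnorm(1, profile$duration_mean, profile$duration_sd)),
    f0_start_hz = level * (1 + slope),
    f0_end_hz = level * (1 - slope),
    jitter_frac = min(0.19, max(0, stats::rnorm(1, profile$jitter_mean, profile$jitter_sd))),
    formants_hz = base * fsc,
    bandwidths_hz = c(80, 120, 160, 220, 280),
    noise_db = stats::rnorm(1, profile$noise_db_mean, profile$noise_db_sd),
    sample_rate_hz = sample_rate_hz
  )
}

#' Synthesize a sentence corpus for a set of speakers
#'
#' For each speaker, draws \code{n_sentences} voice specs from the speaker's
#' per-parameter distributions and synthesizes each sentence. Deterministic
#' given \code{(profiles, n_sentences, seed)}.
#'
#' @param profiles A \code{\link{speaker_profiles}} data frame (>= 2 rows).
#' @param n_sentences Sentences per speaker (>= 1).
#' @param seed Integer seed.
#' @param sample_rate_hz Sampling rate for all sentences.
#' @return A list of class \code{"voice_corpus"} with elements
#'   \code{manifest} (data frame: speaker_id, gender, sentence_id plus
#'   ground-truth spec columns) and \code{waves} (list of waveforms, one per
#'   manifest row).
#' @export
sample_corpus <- function(profiles, n_sentences, seed = 1L,
                          sample_rate_hz = 44100) {
  if (is.null(profiles) || nrow(profiles) < 2) {
    stop("need at least 2 speaker profiles", call. = FALSE)
  }
  if (n_sentences < 1) stop("n_sentences must be >= 1", call. = FALSE)
  rows <- list()
  waves <- list()
  k <- 0L
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    for (s in seq_len(n_sentences)) {
      k <- k + 1L
      sent_seed <- (seed + 7919L * i + 104729L * s) %% .Machine$integer.max
      spec <- with_seed(sent_seed, draw_sentence_spec(prof, sample_rate_hz))
      waves[[k]] <- synthesize_voice(spec, seed = sent_seed)
      rows[[k]] <- data.frame(
        speaker_id = prof$speaker_id,
        gender = prof$gender,
        sentence_id = sprintf("%s_sent%02d", prof$speaker_id, s),
        duration_s = spec$duration_s,
        f0_start_hz = spec$f0_start_hz,
        f0_end_hz = spec$f0_end_hz,
        jitter_frac = spec$jitter_frac,
        noise_db = spec$noise_db,
        dF_true = (spec$formants_hz[5] - spec$formants_hz[1]) / 4,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(manifest = do.call(rbind, rows), waves = waves)
  class(out) <- "voice_corpus"
  out
}

#' @export
print.voice_corpus <- function(x, ...) {
  cat(sprintf(
    "<voice_corpus: %d sentences from %d speakers>\n",
    nrow(x$manifest), length(unique(x$manifest$speaker_id))
  ))
  invisible(x)
}
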