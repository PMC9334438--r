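#' Jitter and cycle-count features from a pulse sequence
#'
#' \code{ppj} is local (period-to-period) jitter: the mean absolute
#' difference between consecutive glottal periods divided by the mean period.
#' Periods spanning a gap between voiced regions (longer than 1.5 times the
#' median period) are excluded. \code{ppp} is the number of voice cycles
#' (pulses); \code{ppm} the mean number of cycles per second of voiced
#' signal.
#'
#' @param s A \code{\link{extract_pulses}} result.
#' @param p The matching \code{\link{track_pitch}} result (unused beyond the
#'   voiced duration already carried by \code{s}; accepted for symmetry).
#' @return Named list \code{ppj}, \code{ppp}, \code{ppm}; \code{ppj} is
#'   \code{NA} with fewer than 3 pulses.
#' @export
jitter_features <- function(s, p = NULL) {
  times <- s$pulse_times
  ppp <- length(times)
  vd <- s$voiced_duration
  ppm <- if (ppp > 0 && vd > 0) ppp / vd else NA_real_
  if (ppp < 3) {
    return(list(ppj = NA_real_, ppp = as.numeric(ppp), ppm = ppm))
  }
  per <- diff(times)
  ok <- per <= 1.5 * stats::median(per)
  pair_ok <- ok[-length(ok)] & ok[-1]
  dif <- abs(diff(per))[pair_ok]
  ppj <- if (length(dif) >= 1 && any(ok)) mean(dif) / mean(per[ok]) else NA_real_
  list(ppj = ppj, ppp = as.numeric(ppp), ppm = ppm)
}

#' Harmonics-to-noise ratio statistics
#'
#' Per voiced frame, the harmonicity is \code{10*log10(r / (1 - r))} where
#' \code{r} is the normalized autocorrelation at the pitch lag (the fraction
#' of frame power that is periodic). Frame values are capped at +40 dB;
#' outputs are the mean, SD and maximum over voiced frames.
#'
#' When the waveform is supplied, the autocorrelation is recomputed with a
#' longer window (\code{hnr_window}, default 80 ms): the finite-window bias
#' of the normalized autocorrelation scales as the inverse window length,
#' and the 40 ms pitch window would cap measurable HNR near 27 dB.
#'
#' @param w A \code{\link{waveform}}, or \code{NULL} to reuse the
#'   autocorrelation peaks already carried by \code{p}.
#' @param p A \code{\link{track_pitch}} result.
#' @param hnr_window Analysis window for the HNR pass, seconds.
#' @return Named list \code{HNR}, \code{HNR_SD}, \code{HNR_max} (dB), all
#'   \code{NA} when nothing is voiced.
#' @export
harmonicity <- function(w, p, hnr_window = 0.08) {
  if (!is.null(w) && hnr_window > 0) {
    s <- attr(p, "settings") %||% feature_settings()
    s$frame_window <- hnr_window
    p2 <- track_pitch(w, s$floor_hz, s$ceiling_hz, s)
    if (any(p2$voiced)) p <- p2
  }
  r <- p$r_peak[p$voiced]
  if (length(r) == 0) {
    return(list(HNR = NA_real_, HNR_SD = NA_real_, HNR_max = NA_real_))
  }
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  h <- pmin(10 * log10(r / (1 - r)), 40)
  list(
    HNR = mean(h),
    HNR_SD = if (length(h) > 1) stats::sd(h) else 0,
    HNR_max = max(h)
  )
}

# Welch-averaged one-sided power spectrum (long-term average spectrum).
# Returns freq (Hz) and power for bins 0..Nyquist.
ltas <- function(w, frame_window = 0.04, overlap = 0.5) {
  fs <- w$sample_rate_hz
  x <- w$samples
  nw <- min(length(x), round(frame_window * fs))
  step <- max(1L, round(nw * (1 - overlap)))
  nfft <- 2^ceiling(log2(nw))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  acc <- numeric(nfft / 2 + 1)
  used <- 0L
  for (s in starts) {
    fr <- x[s:(s + nw - 1L)]
    if (all(fr == 0)) next
    X <- stats::fft(c(fr * win, numeric(nfft - nw)))
    acc <- acc + Mod(X[seq_len(nfft / 2 + 1)])^2
    used <- used + 1L
  }
  if (used == 0L) stop("signal has zero energy", call. = FALSE)
  list(freq = (0:(nfft / 2)) * fs / nfft, power = acc / used)
}

#' Wiener entropy of the long-term spectrum
#'
#' The log ratio of the geometric to the arithmetic mean of the power
#' spectrum averaged over analysis frames. Zero for a perfectly flat (white)
#' spectrum, strongly negative for a line (tonal) spectrum.
#'
#' @param w A \code{\link{waveform}} with nonzero energy.
#' @return Scalar \code{ent} (natural log, \code{<= 0}).
#' @export
wiener_entropy <- function(w) {
  sp <- ltas(w)
  p <- sp$power[-1]           # drop DC
  p <- pmax(p, .Machine$double.xmin)
  mean(log(p)) - log(mean(p))
}

#' Spectral moment and band-energy features
#'
#' Treats the long-term (Welch-averaged) power spectrum as a distribution
#' over frequency. \code{CG} is its mean frequency, \code{DevFreq} its SD,
#' \code{Sk} and \code{Kr} the standardized skewness and excess kurtosis,
#' \code{cmoment} the non-normalized third central moment (Hz^3).
#' \code{EnergyDiff} is the dB ratio of energy in the 0--2000 Hz band to the
#' 2000--6000 Hz band; \code{BEn} the proportion of total energy between
#' 2000 and 4000 Hz.
#'
#' @param w A \code{\link{waveform}} sampled at >= 12 kHz.
#' @return Named list \code{CG}, \code{DevFreq}, \code{Sk}, \code{Kr},
#'   \code{cmoment}, \code{EnergyDiff}, \code{BEn}.
#' @export
spectral_shape <- function(w) {
  if (w$sample_rate_hz < 12000) {
    stop("sample rate must be >= 12 kHz for the 6 kHz band edge", call. = FALSE)
  }
  sp <- ltas(w)
  f <- sp$freq
  p <- sp$power
  tot <- sum(p)
  if (tot <= 0) stop("signal has zero energy", call. = FALSE)
  pw <- p / tot
  cg <- sum(pw * f)
  mu2 <- sum(pw * (f - cg)^2)
  mu3 <- sum(pw * (f - cg)^3)
  mu4 <- sum(pw * (f - cg)^4)
  e_low <- sum(p[f < 2000])
  e_high <- sum(p[f >= 2000 & f < 6000])
  e_band <- sum(p[f >= 2000 & f < 4000])
  list(
    CG = cg,
    DevFreq = sqrt(mu2),
    Sk = if (mu2 > 0) mu3 / mu2^1.5 else NA_real_,
    Kr = if (mu2 > 0) mu4 / mu2^2 - 3 else NA_real_,
    cmoment = mu3,
    EnergyDiff = 10 * log10(e_low / max(e_high, .Machine$double.xmin)),
    BEn = e_band / tot
  )
}

#' Formant dispersion from the harmonic spectral envelope
#'
#' Formants of a voiced signal are resonances of the spectral envelope, but
#' the spectrum of periodic phonation only carries envelope information at
#' the harmonics. The estimator therefore (1) pre-emphasizes the signal
#' (first difference, +6 dB/octave, to undo glottal spectral tilt),
#' (2) forms a fine-resolution long-term average power spectrum from 80 ms
#' frames, (3) samples the envelope at each harmonic of the tracked mean f0
#' (strongest bin within 0.45 f0 of the nominal harmonic), and (4) picks the
#' first five local maxima of the log harmonic-amplitude series, refining
#' each by quadratic interpolation over neighbouring harmonics. Formant
#' dispersion is the mean of the four consecutive differences, i.e.
#' \code{(F5 - F1) / 4}.
#'
#' @param w A \code{\link{waveform}}.
#' @param p Its \code{\link{track_pitch}} result; the voiced-frame mean f0
#'   defines the harmonic grid.
#' @param gender_ceiling_hz Formant search ceiling: 5500 Hz is typical for
#'   female voices, 5000 Hz for male voices.
#' @return Scalar \code{dF} in Hz, with attribute \code{"formants_hz"} (the
#'   five formant estimates); \code{NA} with a warning when five formants
#'   cannot be resolved.
#' @export
formant_dispersion <- function(w, p, gender_ceiling_hz = 5500) {
  if (!any(p$voiced)) {
    warning("no voiced frames; formant dispersion is missing")
    return(NA_real_)
  }
  fs <- w$sample_rate_hz
  alpha <- exp(-2 * pi * 50 / fs)
  x <- w$samples
  x <- c(x[1], x[-1] - alpha * x[-length(x)])
  nw <- min(length(x), round(0.08 * fs))
  nfft <- 2^ceiling(log2(nw))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  starts <- seq(1L, length(x) - nw + 1L, by = max(1L, nw %/% 2))
  acc <- numeric(nfft / 2 + 1)
  for (s in starts) {
    X <- stats::fft(c(x[s:(s + nw - 1L)] * win, numeric(nfft - nw)))
    acc <- acc + Mod(X[seq_len(nfft / 2 + 1)])^2
  }
  freq <- (0:(nfft / 2)) * fs / nfft
  f0m <- mean(p$f0_hz[p$voiced])
  k_max <- floor(min(gender_ceiling_hz, fs / 2 - 50) / f0m)
  if (k_max < 6) {
    warning("fewer than 5 formants resolvable; formant dispersion is missing")
    return(NA_real_)
  }
  pk_f <- pk_p <- numeric(0)
  for (k in seq_len(k_max)) {
    sel <- which(freq > (k - 0.45) * f0m & freq < (k + 0.45) * f0m)
    if (!length(sel)) next
    j <- sel[which.max(acc[sel])]
    pk_f <- c(pk_f, freq[j])
    pk_p <- c(pk_p, log(max(acc[j], .Machine$double.xmin)))
  }
  # detrend the log harmonic-amplitude series (continuum removal): a weak
  # high formant riding a steep skirt shows up as positive curvature even
  # when it is barely a local maximum of the raw envelope
  n <- length(pk_p)
  hw2 <- max(2L, ceiling(700 / f0m))
  bg <- vapply(seq_len(n), function(i) {
    mean(pk_p[max(1L, i - hw2):min(n, i + hw2)])
  }, numeric(1))
  res <- pk_p - bg
  # local maxima of the residual; the search half-width adapts to harmonic
  # density (roughly half a typical formant spacing)
  hw <- max(1L, floor(400 / f0m))
  ff <- numeric(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - hw)
    hi <- min(n, i + hw)
    if (i == 1L || i == n) next  # series endpoints are not resonance peaks
    if (res[i] < max(res[lo:hi])) next
    if (i > lo && res[i] == max(res[lo:(i - 1)])) next  # plateau tie
    ym <- res[i - 1]; y0 <- res[i]; yp <- res[i + 1]
    den <- ym - 2 * y0 + yp
    d <- if (abs(den) > 1e-12) 0.5 * (ym - yp) / den else 0
    d <- max(min(d, 0.5), -0.5)
    ff <- c(ff, pk_f[i] + d * f0m)
  }
  ff <- ff[ff > 100 & ff < gender_ceiling_hz]
  if (length(ff) < 5) {
    warning("fewer than 5 formants resolvable; formant dispersion is missing")
    return(NA_real_)
  }
  out <- mean(diff(ff[1:5]))
  attr(out, "formants_hz") <- ff[1:5]
  out
}

#' Canonical feature order of the acoustic battery
#'
#' The 25 acoustic parameters in table order: ten fundamental-frequency
#' measures, seven noisiness measures, eight spectral-energy measures.
#'
#' @return Character vector of feature names.
#' @export
feature_names <- function() {
  c(
    "f0_mean", "f0_range", "f0_change", "f0_sd", "f0_max", "f0_min",
    "f0_mnpozr", "f0_mxpozr", "f0_end", "f0_st",
    "ppj", "ppp", "ppm", "ent", "HNR", "HNR_SD", "HNR_max",
    "dF", "CG", "DevFreq", "EnergyDiff", "Sk", "Kr", "cmoment", "BEn"
  )
}

#' Extract the full acoustic feature battery from one sentence
#'
#' Composes pitch tracking, f0 statistics, pulse extraction, jitter,
#' harmonicity, Wiener entropy, spectral moments and formant dispersion into
#' the 25-parameter feature vector. Missing components (e.g. a fully
#' unvoiced signal) propagate as \code{NA}.
#'
#' @param w A \code{\link{waveform}}.
#' @param settings A \code{\link{feature_settings}} object.
#' @return A named list of class \code{"feature_vector"} with the fields of
#'   \code{\link{feature_names}}, in canonical order.
#' @export
extract_features <- function(w, settings = feature_settings()) {
  stopifnot(inherits(w, "waveform"))
  if (all(w$samples == 0)) {
    warning("silent waveform; all features missing")
    out <- stats::setNames(as.list(rep(NA_real_, 25)), feature_names())
    class(out) <- "feature_vector"
    return(out)
  }
  p <- track_pitch(w, settings$floor_hz, settings$ceiling_hz, settings)
  f0s <- suppressWarnings(f0_statistics(p))
  pulses <- extract_pulses(w, p)
  jit <- jitter_features(pulses, p)
  hnr <- harmonicity(w, p)
  ent <- wiener_entropy(w)
  spec <- spectral_shape(w)
  dF <- suppressWarnings(
    formant_dispersion(w, p, settings$formant_ceiling_hz)
  )
  out <- c(f0s, jit, list(ent = ent), hnr, list(dF = as.numeric(dF)), spec)
  out <- out[feature_names()]
  class(out) <- "feature_vector"
  out
}

#' Extract features for every sentence of a corpus
#'
#' @param corpus A \code{\link{sample_corpus}} result.
#' @param settings A \code{\link{feature_settings}} object; the formant
#'   ceiling is set per sentence from the speaker's gender (5500 Hz female,
#'   5000 Hz male) unless \code{fixed_ceiling} is \code{TRUE}.
#' @param fixed_ceiling Use \code{settings$formant_ceiling_hz} for all rows.
#' @return A data frame: manifest columns plus one column per feature, one
#'   row per (speaker, sentence).
#' @export
extract_features_corpus <- function(corpus, settings = feature_settings(),
                                    fixed_ceiling = FALSE) {
  man <- corpus$manifest
  feats <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    s <- settings
    if (!fixed_ceiling) {
      s$formant_ceiling_hz <- if (man$gender[i] == "male") 5000 else 5500
    }
    fv <- suppressWarnings(extract_features(corpus$waves[[i]], s))
    feats[[i]] <- as.data.frame(unclass(fv))
  }
  cbind(man, do.call(rbind, feats))
}
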