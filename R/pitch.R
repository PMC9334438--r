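#' Default analysis settings for the acoustic feature battery
#'
#' Conventional speech-analysis defaults: 40 ms analysis window, 10 ms step,
#' a 75--500 Hz pitch search range, and a voicing decision at a normalized
#' autocorrelation of 0.45. The formant ceiling defaults to 5500 Hz (typical
#' for female voices; use 5000 Hz for male voices).
#'
#' @param floor_hz,ceiling_hz Pitch search range, Hz.
#' @param frame_step Analysis step, seconds.
#' @param frame_window Analysis window length, seconds.
#' @param voicing_threshold Normalized-autocorrelation threshold for the
#'   voiced/unvoiced decision.
#' @param formant_ceiling_hz Upper frequency limit for formant search, Hz.
#' @return A list of class \code{"feature_settings"}.
#' @export
feature_settings <- function(floor_hz = 75, ceiling_hz = 500,
                             frame_step = 0.01, frame_window = 0.04,
                             voicing_threshold = 0.45,
                             formant_ceiling_hz = 5500) {
  stopifnot(floor_hz > 0, ceiling_hz > floor_hz)
  structure(
    list(
      floor_hz = floor_hz, ceiling_hz = ceiling_hz,
      frame_step = frame_step, frame_window = frame_window,
      voicing_threshold = voicing_threshold,
      formant_ceiling_hz = formant_ceiling_hz
    ),
    class = "feature_settings"
  )
}

# Normalized autocorrelation of one windowed frame via FFT, divided by the
# window's own autocorrelation (removes the taper bias).
frame_acf <- function(x, w_acf, nfft) {
  x <- x - mean(x)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  r <- Re(stats::fft(X * Conj(X), inverse = TRUE))
  if (r[1] <= 0) return(NULL)
  r <- r / r[1]
  r[seq_along(w_acf)] / w_acf
}

#' Track pitch by frame-wise autocorrelation
#'
#' Short-term autocorrelation pitch analysis with a tapered window: each
#' frame's autocorrelation is normalized by the window autocorrelation, the
#' strongest peak in the candidate lag range is refined by parabolic
#' interpolation, and a frame is voiced when the peak exceeds
#' \code{voicing_threshold}. Unvoiced frames carry \code{NA} f0.
#'
#' @param w A \code{\link{waveform}}.
#' @param floor_hz,ceiling_hz Pitch search range; \code{ceiling_hz} must be
#'   below Nyquist.
#' @param settings Optional \code{\link{feature_settings}} providing frame
#'   step/window and the voicing threshold.
#' @return An object of class \code{"pitch_track"}: data frame fields
#'   \code{frame_times}, \code{f0_hz}, \code{voiced}, \code{r_peak}
#'   (autocorrelation at the pitch lag, for harmonicity), plus attribute
#'   \code{call_length} (signal duration, seconds).
#' @export
track_pitch <- function(w, floor_hz = 75, ceiling_hz = 500,
                        settings = feature_settings(floor_hz, ceiling_hz)) {
  stopifnot(inherits(w, "waveform"))
  fs <- w$sample_rate_hz
  if (!(floor_hz < ceiling_hz && ceiling_hz < fs / 2)) {
    stop("need floor_hz < ceiling_hz < Nyquist", call. = FALSE)
  }
  x <- w$samples
  nw <- round(settings$frame_window * fs)
  step <- round(settings$frame_step * fs)
  lag_min <- max(2L, floor(fs / ceiling_hz))
  lag_max <- ceiling(fs / floor_hz)
  call_length <- length(x) / fs

  empty <- function() {
    structure(
      list(frame_times = numeric(0), f0_hz = numeric(0),
           voiced = logical(0), r_peak = numeric(0)),
      call_length = call_length, class = "pitch_track"
    )
  }
  if (length(x) < nw || lag_max >= nw) return(empty())

  starts <- seq(1L, length(x) - nw + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann
  nfft <- 2^ceiling(log2(2L * nw))
  Wf <- stats::fft(c(win, numeric(nfft - nw)))
  w_acf <- Re(stats::fft(Wf * Conj(Wf), inverse = TRUE))
  w_acf <- (w_acf / w_acf[1])[seq_len(lag_max + 2L)]

  n_fr <- length(starts)
  f0 <- rep(NA_real_, n_fr)
  rpk <- rep(NA_real_, n_fr)
  glob_rms <- sqrt(mean(x^2))
  peaks <- vector("list", n_fr)   # per frame: candidate peak lags and r
  choice <- rep(NA_integer_, n_fr)
  acfs <- vector("list", n_fr)
  for (i in seq_len(n_fr)) {
    fr <- x[starts[i]:(starts[i] + nw - 1L)]
    if (sqrt(mean(fr^2)) < 1e-4 * max(glob_rms, 1e-12)) next
    r <- frame_acf(fr * win, w_acf, nfft)
    if (is.null(r)) next
    acfs[[i]] <- r
    band <- r[(lag_min + 1L):(lag_max + 1L)]  # r[k+1] is lag k
    d <- diff(band)
    pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
    if (!length(pk)) pk <- which.max(band)
    peaks[[i]] <- list(lag = lag_min + pk - 1L, r = band[pk])
    # first pass: octave cost against picking multiples of the true period
    # (under jitter the peak at twice the period is the higher one because
    # period variance averages out over two cycles)
    score <- band[pk] - 0.07 * log2((lag_min + pk - 1L) / lag_min)
    choice[i] <- pk[which.max(score)] + lag_min - 1L
  }
  # second pass: re-anchor every frame to the sentence-median period, which
  # removes isolated octave and formant-ringing errors
  prelim_r <- vapply(seq_len(n_fr), function(i) {
    if (is.na(choice[i])) NA_real_ else peaks[[i]]$r[match(choice[i], peaks[[i]]$lag)]
  }, numeric(1))
  good <- !is.na(prelim_r) & prelim_r >= settings$voicing_threshold
  if (any(good)) {
    med_lag <- stats::median(choice[good])
    for (i in seq_len(n_fr)) {
      if (is.null(peaks[[i]])) next
      ok <- peaks[[i]]$lag >= med_lag / 1.4 & peaks[[i]]$lag <= med_lag * 1.4
      if (any(ok)) {
        cand_r <- peaks[[i]]$r
        cand_r[!ok] <- -Inf
        choice[i] <- peaks[[i]]$lag[which.max(cand_r)]
      }
    }
  }
  for (i in seq_len(n_fr)) {
    if (is.na(choice[i]) || is.null(acfs[[i]])) next
    r <- acfs[[i]]
    lag0 <- choice[i]
    # parabolic refinement over neighbouring lags
    if (lag0 > lag_min && lag0 < lag_max) {
      ym <- r[lag0]; y0 <- r[lag0 + 1L]; yp <- r[lag0 + 2L]
      denom <- ym - 2 * y0 + yp
      d <- if (abs(denom) > 1e-12) 0.5 * (ym - yp) / denom else 0
      d <- max(min(d, 0.5), -0.5)
      lag_hat <- lag0 + d
      r_hat <- y0 - 0.25 * (ym - yp) * d
    } else {
      lag_hat <- lag0
      r_hat <- r[lag0 + 1L]
    }
    f0[i] <- fs / lag_hat
    rpk[i] <- min(r_hat, 1 - 1e-6)
  }
  voiced <- !is.na(rpk) & rpk >= settings$voicing_threshold &
    !is.na(f0) & f0 >= floor_hz & f0 <= ceiling_hz
  structure(
    list(
      frame_times = (starts - 1L + nw / 2) / fs,
      f0_hz = ifelse(voiced, f0, NA_real_),
      voiced = voiced,
      r_peak = rpk
    ),
    call_length = call_length,
    frame_step = settings$frame_step,
    settings = settings,
    class = "pitch_track"
  )
}

#' @export
print.pitch_track <- function(x, ...) {
  cat(sprintf(
    "<pitch_track: %d frames, %d voiced, call length %.3f s>\n",
    length(x$frame_times), sum(x$voiced), attr(x, "call_length")
  ))
  invisible(x)
}

#' Fundamental-frequency statistics of a pitch track
#'
#' Summary statistics over voiced frames: mean, SD, minimum, maximum, start
#' (first voiced frame) and end (last voiced frame) f0; the derived range
#' (max - min) and change (end - start); and the relative positions of the
#' f0 minimum and maximum (frame time divided by call length, earliest frame
#' on ties).
#'
#' @param p A \code{\link{track_pitch}} result.
#' @return Named list with \code{f0_mean}, \code{f0_range}, \code{f0_change},
#'   \code{f0_sd}, \code{f0_max}, \code{f0_min}, \code{f0_mnpozr},
#'   \code{f0_mxpozr}, \code{f0_end}, \code{f0_st}. All \code{NA} (with a
#'   warning) when fewer than 2 voiced frames exist.
#' @export
f0_statistics <- function(p) {
  miss <- list(
    f0_mean = NA_real_, f0_range = NA_real_, f0_change = NA_real_,
    f0_sd = NA_real_, f0_max = NA_real_, f0_min = NA_real_,
    f0_mnpozr = NA_real_, f0_mxpozr = NA_real_,
    f0_end = NA_real_, f0_st = NA_real_
  )
  v <- which(p$voiced)
  if (length(v) < 2) {
    warning("fewer than 2 voiced frames; f0 statistics are missing")
    return(miss)
  }
  f0 <- p$f0_hz[v]
  t <- p$frame_times[v]
  cl <- attr(p, "call_length")
  i_min <- which.min(f0)
  i_max <- which.max(f0)
  list(
    f0_mean = mean(f0),
    f0_range = max(f0) - min(f0),
    f0_change = f0[length(f0)] - f0[1],
    f0_sd = stats::sd(f0),
    f0_max = max(f0),
    f0_min = min(f0),
    f0_mnpozr = t[i_min] / cl,
    f0_mxpozr = t[i_max] / cl,
    f0_end = f0[length(f0)],
    f0_st = f0[1]
  )
}

#' Extract glottal pulse epochs guided by the pitch track
#'
#' Walks through each voiced region picking one amplitude peak per glottal
#' cycle: starting from the strongest peak of the region, the next epoch is
#' searched within 0.75--1.35 local periods of the previous one (and
#' symmetrically when walking backwards). Peak positions are refined to
#' sub-sample precision by parabolic interpolation.
#'
#' @param w A \code{\link{waveform}}.
#' @param p Its \code{\link{track_pitch}} result.
#' @return Object of class \code{"pulse_sequence"}: list with
#'   \code{pulse_times} (seconds, strictly increasing; empty when nothing is
#'   voiced) and \code{voiced_duration} (total voiced time, seconds).
#' @export
extract_pulses <- function(w, p) {
  fs <- w$sample_rate_hz
  x <- w$samples
  step <- attr(p, "frame_step") %||% 0.01
  v <- p$voiced
  out <- numeric(0)
  if (any(v)) {
    # contiguous voiced regions (by frame index)
    runs <- rle(v)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    f0_interp <- function(t) {
      vi <- which(v)
      stats::approx(p$frame_times[vi], p$f0_hz[vi], xout = t, rule = 2)$y
    }
    refine <- function(i) {
      if (i <= 1L || i >= length(x)) return(i - 1)
      ym <- x[i - 1L]; y0 <- x[i]; yp <- x[i + 1L]
      denom <- ym - 2 * y0 + yp
      d <- if (abs(denom) > 1e-12) 0.5 * (ym - yp) / denom else 0
      (i - 1) + max(min(d, 0.5), -0.5)
    }
    for (rg in which(runs$values)) {
      t0 <- p$frame_times[starts[rg]] - step / 2
      t1 <- p$frame_times[ends[rg]] + step / 2
      i0 <- max(1L, floor(t0 * fs) + 1L)
      i1 <- min(length(x), ceiling(t1 * fs))
      if (i1 - i0 < 4L) next
      seg <- x[i0:i1]
      anchor <- i0 + which.max(seg) - 1L
      pulses <- refine(anchor) / fs
      # forward walk
      t <- pulses
      repeat {
        T_loc <- 1 / f0_interp(t)
        lo <- floor((t + 0.75 * T_loc) * fs) + 1L
        hi <- ceiling((t + 1.35 * T_loc) * fs) + 1L
        if (lo > i1) break
        hi <- min(hi, i1)
        if (hi <= lo) break
        j <- lo + which.max(x[lo:hi]) - 1L
        t_new <- refine(j) / fs
        if (t_new <= t) break
        pulses <- c(pulses, t_new)
        t <- t_new
      }
      # backward walk
      t <- pulses[1]
      repeat {
        T_loc <- 1 / f0_interp(t)
        lo <- floor((t - 1.35 * T_loc) * fs) + 1L
        hi <- ceiling((t - 0.75 * T_loc) * fs) + 1L
        if (hi < i0) break
        lo <- max(lo, i0)
        if (hi <= lo) break
        j <- lo + which.max(x[lo:hi]) - 1L
        t_new <- refine(j) / fs
        if (t_new >= t) break
        pulses <- c(t_new, pulses)
        t <- t_new
      }
      out <- c(out, pulses)
    }
    out <- sort(out)
    out <- out[c(TRUE, diff(out) > 1e-6)]
  }
  structure(
    list(pulse_times = out, voiced_duration = sum(v) * step),
    class = "pulse_sequence"
  )
}
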