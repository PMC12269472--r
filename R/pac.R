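#' Frequency grid for the maximum-PAC search
#'
#' The search space for the per-vertex maximum phase-amplitude coupling: a
#' low-frequency phase grid within \[2,30\] Hz and a high-gamma amplitude grid
#' within \[80,150\] Hz. Phase bands have half-width `max(1, f/4)` Hz. The
#' amplitude band half-width adapts to the phase frequency of the pair under
#' test: it is the smallest member of `amp_widths` that is at least
#' `f_phase + amp_pad` Hz, so the modulation sidebands at `f_amp +/- f_phase`
#' always pass while neighbouring amplitude cells remain distinguishable.
#'
#' @param phase_freqs Phase frequencies in Hz (default 2-30 in 1 Hz steps).
#' @param amp_freqs Amplitude frequencies in Hz (default 80-150 in 5 Hz steps).
#' @param amp_widths Candidate amplitude half-widths in Hz.
#' @param amp_pad Margin added to the phase frequency when choosing the
#'   amplitude half-width.
#' @return An object of class `pac_grid`.
#' @export
pac_grid <- function(phase_freqs = 2:30,
                     amp_freqs = seq(80, 150, by = 5),
                     amp_widths = c(12, 19, 35),
                     amp_pad = 5) {
  stopifnot(all(diff(phase_freqs) > 0), all(diff(amp_freqs) > 0),
            min(phase_freqs) >= 2, max(phase_freqs) <= 30,
            min(amp_freqs) >= 80, max(amp_freqs) <= 150)
  widths <- sort(amp_widths)
  if (max(phase_freqs) + amp_pad > max(widths)) {
    stop("amp_widths too small for the highest phase frequency")
  }
  cls <- vapply(phase_freqs, function(f) which(widths >= f + amp_pad)[1], 1L)
  structure(list(
    phase_freqs = phase_freqs,
    amp_freqs = amp_freqs,
    phase_bw = pmax(1, phase_freqs / 4),
    amp_widths = widths,
    amp_class = cls,          # width class per phase frequency
    amp_pad = amp_pad
  ), class = "pac_grid")
}

# ---- internal spectral machinery -------------------------------------------
# Bands are extracted with a zero-phase frequency-domain bandpass whose
# positive-frequency content is inverted directly into the analytic signal,
# decimated to an internal analysis rate of ~200 Hz (exact when the band is
# fully below the decimated Nyquist; amplitude bands are shifted to baseband
# first, which leaves the envelope untouched).

.analysis_decim <- function(n, fs, target = 150, min_rate = NULL) {
  r <- max(1L, floor(fs / target))
  if (!is.null(min_rate)) r <- min(r, max(1L, floor(fs / min_rate)))
  while (r > 1L && n %% r != 0L) r <- r - 1L
  r
}

# Selected positive-frequency bins (1-based row indices) for [f1, f2].
.band_bins <- function(n, fs, f1, f2) {
  kmax <- floor(n / 2)
  klo <- max(1L, ceiling(f1 * n / fs))
  khi <- min(kmax - 1L, floor(f2 * n / fs))
  if (khi < klo) integer(0) else (klo:khi) + 1L
}

# One length-M spectrum column holding the doubled band bins, optionally
# shifted to baseband (for amplitude envelopes).
.band_column <- function(M, spec, bins, shift) {
  col <- complex(M)
  if (length(bins)) {
    if (shift) {
      col[seq_along(bins)] <- 2 * spec[bins]
    } else {
      col[bins] <- 2 * spec[bins]
    }
  }
  col
}

#' Direct phase-amplitude coupling estimator
#'
#' The direct estimator
#' \deqn{PAC = \frac{|\sum_t a(t) e^{i\phi(t)}|}{\sqrt{N}\sqrt{\sum_t a(t)^2}}}
#' from an amplitude envelope `amp` and an instantaneous phase `phase`
#' (radians) sampled at the same times. Bounded in \[0,1\] by the
#' Cauchy-Schwarz inequality; an all-zero envelope returns 0.
#'
#' @param amp Non-negative amplitude envelope.
#' @param phase Instantaneous phase in radians, same length.
#' @return PAC value in \[0,1\].
#' @export
pac_direct <- function(amp, phase) {
  stopifnot(length(amp) == length(phase))
  den <- sqrt(length(amp) * sum(amp^2))
  if (den == 0) return(0)
  num <- Mod(sum(amp * exp(1i * phase)))
  num / den
}

#' Estimate PAC between one phase and one amplitude frequency
#'
#' Bandpasses `signal` around `f_phase` and `f_amp` (zero-phase), takes the
#' analytic phase of the slow band and the analytic amplitude of the fast
#' band, and evaluates the direct estimator. Invariant to overall scaling and
#' to constant offsets of the input.
#'
#' @param signal Numeric vector, a single-vertex time series.
#' @param f_phase Phase frequency in Hz.
#' @param f_amp Amplitude frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param phase_bw Half-width of the phase band (default `max(1, f_phase/4)`).
#' @param amp_bw Half-width of the amplitude band (default the grid rule,
#'   smallest of `c(12,19,35)` at least `f_phase + 5`).
#' @return PAC value in \[0,1\].
#' @export
estimate_pac <- function(signal, f_phase, f_amp, fs,
                         phase_bw = NULL, amp_bw = NULL) {
  n <- length(signal)
  if (n < 10 * fs / f_phase) {
    stop("signal too short: need at least 10 cycles of the phase frequency")
  }
  if (is.null(phase_bw)) phase_bw <- max(1, f_phase / 4)
  if (is.null(amp_bw)) {
    w <- c(12, 19, 35)
    amp_bw <- w[which(w >= f_phase + 5)[1]]
  }
  if (fs <= 2 * (f_amp + amp_bw)) {
    stop("sampling rate too low for the amplitude band (aliasing)")
  }
  r <- .analysis_decim(n, fs)
  M <- n %/% r
  spec <- stats::fft(signal)
  S <- cbind(
    .band_column(M, spec, .band_bins(n, fs, f_phase - phase_bw, f_phase + phase_bw), shift = FALSE),
    .band_column(M, spec, .band_bins(n, fs, f_amp - amp_bw, f_amp + amp_bw), shift = TRUE)
  )
  z <- stats::mvfft(S, inverse = TRUE) / n
  amp <- Mod(z[, 2L])
  # an amplitude band carrying only round-off residue counts as all-zero
  if (sum(amp^2) <= 1e-20 * sum(signal^2) / length(signal) * M) return(0)
  pac_direct(amp, Arg(z[, 1L]))
}

# Grid search over one recording matrix (vertices x samples).
# Returns list(best = data.frame(vertex, f_phase, f_amp, pac),
#              pac_array = [n_phase x n_amp x n_vertex] if keep_array).
.pac_grid_search <- function(data, fs, grid, keep_array = FALSE) {
  stopifnot(inherits(grid, "pac_grid"))
  nv <- nrow(data)
  n <- ncol(data)
  np <- length(grid$phase_freqs)
  na <- length(grid$amp_freqs)
  classes_used <- sort(unique(grid$amp_class))
  if (fs <= 2 * (max(grid$amp_freqs) + grid$amp_widths[max(classes_used)])) {
    stop("sampling rate too low for the widest amplitude band (aliasing)")
  }
  if (n < 10 * fs / min(grid$phase_freqs)) {
    stop("signal too short: need at least 10 cycles of the slowest phase frequency")
  }
  widest <- grid$amp_widths[max(classes_used)]
  max_needed <- max(max(grid$phase_freqs + grid$phase_bw), 2 * widest) + 5
  r <- .analysis_decim(n, fs, min_rate = 2 * max_needed)
  M <- n %/% r

  # band layout: phase bands first, then amp bands per width class
  amp_a <- rep(seq_len(na), times = length(classes_used))
  amp_cls <- rep(classes_used, each = na)
  ncols <- np + length(amp_a)
  # precomputed source bins and linear destination indices into the M x ncols
  # spectrum matrix (amplitude bands are shifted to baseband)
  src <- integer(0)
  dst <- numeric(0)
  for (i in seq_len(np)) {
    b <- .band_bins(n, fs, grid$phase_freqs[i] - grid$phase_bw[i],
                    grid$phase_freqs[i] + grid$phase_bw[i])
    src <- c(src, b)
    dst <- c(dst, (i - 1) * M + b)
  }
  for (j in seq_along(amp_a)) {
    fa <- grid$amp_freqs[amp_a[j]]
    w <- grid$amp_widths[amp_cls[j]]
    b <- .band_bins(n, fs, fa - w, fa + w)
    src <- c(src, b)
    dst <- c(dst, (np + j - 1) * M + seq_along(b))
  }
  rows_by_phase <- lapply(seq_len(np), function(i) {
    which(amp_cls == grid$amp_class[i])  # already ordered by amp frequency
  })

  best <- data.frame(vertex = seq_len(nv), f_phase = NA_real_,
                     f_amp = NA_real_, pac = NA_real_)
  pac_array <- if (keep_array) array(NA_real_, c(np, na, nv)) else NULL
  S <- matrix(0 + 0i, M, ncols)
  phase_idx <- seq_len(np)
  amp_idx <- np + seq_along(amp_a)

  for (v in seq_len(nv)) {
    spec <- stats::fft(data[v, ])
    S[] <- 0 + 0i
    S[dst] <- (2 / n) * spec[src]
    z <- stats::mvfft(S, inverse = TRUE)
    ph <- z[, phase_idx, drop = FALSE]
    mod <- Mod(ph)
    mod[mod == 0] <- 1
    cosE <- Re(ph) / mod
    sinE <- Im(ph) / mod
    A <- Mod(z[, amp_idx, drop = FALSE])
    den <- sqrt(M * colSums(A^2))
    den[den == 0] <- Inf
    num <- sqrt(crossprod(A, cosE)^2 + crossprod(A, sinE)^2)  # (na*ncls) x np
    pacs <- matrix(0, np, na)
    for (i in seq_len(np)) {
      rows <- rows_by_phase[[i]]
      pacs[i, ] <- num[rows, i] / den[rows]
    }
    if (keep_array) pac_array[, , v] <- pacs
    # argmax with ties toward lowest f_phase, then lowest f_amp
    imax <- which(pacs == max(pacs), arr.ind = TRUE)
    imax <- imax[order(imax[, 1], imax[, 2]), , drop = FALSE][1, ]
    best$f_phase[v] <- grid$phase_freqs[imax[1]]
    best$f_amp[v] <- grid$amp_freqs[imax[2]]
    best$pac[v] <- pacs[imax[1], imax[2]]
  }
  list(best = best, pac_array = pac_array)
}

#' Per-vertex maximum-PAC map
#'
#' Exhaustively evaluates the direct PAC estimator over the full frequency
#' grid for every vertex and returns the argmax pair and its PAC value. Ties
#' are broken deterministically toward the lowest phase frequency, then the
#' lowest amplitude frequency.
#'
#' @param data Vertices x samples matrix (or a `source_recording`).
#' @param fs Sampling rate in Hz (taken from the recording if one is given).
#' @param grid A [pac_grid()].
#' @return A data.frame of class `pac_map` with columns `vertex`, `f_phase`,
#'   `f_amp`, `pac`.
#' @export
pac_map <- function(data, fs = NULL, grid = pac_grid()) {
  if (inherits(data, "source_recording")) {
    fs <- data$fs
    data <- data$data
  }
  res <- .pac_grid_search(data, fs, grid)$best
  class(res) <- c("pac_map", "data.frame")
  res
}

#' Maximum PAC for a single time series
#'
#' @param signal Numeric vector.
#' @param grid A [pac_grid()].
#' @param fs Sampling rate in Hz.
#' @return A list with `f_phase`, `f_amp`, `pac`.
#' @export
find_max_pac <- function(signal, grid = pac_grid(), fs) {
  res <- .pac_grid_search(matrix(signal, nrow = 1L), fs, grid)$best
  list(f_phase = res$f_phase, f_amp = res$f_amp, pac = res$pac)
}

# ---- megPAC synthesis ------------------------------------------------------

# Alternating extrema (strict alternation enforced by keeping the more
# extreme of consecutive same-type candidates) of a narrow-band series.
.alternating_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(idx = integer(0), type = integer(0)))
  dx <- diff(x)
  up <- dx > 0
  cand <- which(up[-(n - 1L)] & !up[-1L]) + 1L       # maxima
  candmin <- which(!up[-(n - 1L)] & up[-1L]) + 1L    # minima
  ext <- rbind(
    data.frame(idx = cand, type = 1L),
    data.frame(idx = candmin, type = -1L)
  )
  ext <- ext[order(ext$idx), , drop = FALSE]
  if (nrow(ext) < 2L) return(ext)
  keep <- rep(TRUE, nrow(ext))
  last <- 1L
  for (i in 2:nrow(ext)) {
    if (ext$type[i] == ext$type[last]) {
      better <- if (ext$type[i] == 1L) x[ext$idx[i]] > x[ext$idx[last]]
                else x[ext$idx[i]] < x[ext$idx[last]]
      if (better) {
        keep[last] <- FALSE
        last <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      last <- i
    }
  }
  ext[keep, , drop = FALSE]
}

#' Synthesize the megPAC series for one vertex
#'
#' Implements the megPAC construction: locate the maxima and minima of the
#' low-frequency (phase-band) component at the vertex's maximum-coupling
#' phase frequency, sample the high-gamma analytic amplitude at those times
#' (signed + at maxima and - at minima when `signed = TRUE`), linearly
#' interpolate between the extrema samples, and resample the result onto a
#' uniform grid at `rate` Hz (default 10 Hz). Samples before the first and
#' after the last extremum are filled with the nearest extremum value.
#'
#' @param signal Numeric vector, single-vertex series.
#' @param f_phase,f_amp The vertex's maximum-coupling frequency pair (Hz).
#' @param fs Sampling rate of `signal` in Hz.
#' @param rate Output rate in Hz.
#' @param signed Use the +/- sign convention at maxima/minima (default TRUE);
#' @param vertex Label used in error messages.
#' @return A list with `series` (length `floor(duration * rate)`), `rate`,
#'   `extrema_times` (seconds) and `extrema_values`.
#' @export
synthesize_megpac <- function(signal, f_phase, f_amp, fs, rate = 10,
                              signed = FALSE, vertex = 1L) {
  n <- length(signal)
  r <- .analysis_decim(n, fs)
  M <- n %/% r
  fs2 <- fs / r
  phase_bw <- max(1, f_phase / 4)
  w <- c(12, 19, 35)
  amp_bw <- w[which(w >= f_phase + 5)[1]]
  spec <- stats::fft(signal)
  S <- cbind(
    .band_column(M, spec, .band_bins(n, fs, f_phase - phase_bw, f_phase + phase_bw), FALSE),
    .band_column(M, spec, .band_bins(n, fs, f_amp - amp_bw, f_amp + amp_bw), TRUE)
  )
  z <- stats::mvfft(S, inverse = TRUE) / n
  low <- Re(z[, 1L])
  amp <- Mod(z[, 2L])
  # a low band carrying only round-off residue has no usable extrema
  degenerate <- sum(low^2) <= 1e-20 * max(sum(signal^2), .Machine$double.xmin) / n * M
  ext <- if (degenerate) data.frame(idx = integer(0), type = integer(0))
         else .alternating_extrema(low)
  if (nrow(ext) < 4L) {
    stop(sprintf("vertex %s: fewer than 4 alternating extrema in the low-frequency component", vertex))
  }
  times <- (ext$idx - 1L) / fs2
  vals <- amp[ext$idx]
  if (signed) vals <- vals * ext$type
  len <- floor(n / fs * rate)
  tout <- (0:(len - 1L)) / rate
  series <- stats::approx(times, vals, xout = tout, rule = 2)$y
  list(series = series, rate = rate,
       extrema_times = times, extrema_values = vals)
}

#' megPAC series for a whole recording
#'
#' Applies [synthesize_megpac()] to every vertex at its maximum-coupling
#' frequency pair from a [pac_map()].
#'
#' @param data Vertices x samples matrix (or a `source_recording`).
#' @param pacmap The recording's `pac_map`.
#' @param fs Sampling rate in Hz.
#' @param rate Output rate in Hz (default 10).
#' @param signed Sign convention switch, see [synthesize_megpac()].
#' @return Vertices x `floor(duration*rate)` matrix.
#' @export
megpac_matrix <- function(data, pacmap, fs = NULL, rate = 10, signed = FALSE) {
  if (inherits(data, "source_recording")) {
    fs <- data$fs
    data <- data$data
  }
  nv <- nrow(data)
  len <- floor(ncol(data) / fs * rate)
  out <- matrix(NA_real_, nv, len)
  for (v in seq_len(nv)) {
    out[v, ] <- synthesize_megpac(data[v, ], pacmap$f_phase[v],
                                  pacmap$f_amp[v], fs, rate = rate,
                                  signed = signed, vertex = v)$series
  }
  out
}
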