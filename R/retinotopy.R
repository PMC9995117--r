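#' Preprocess a phase-encoded retinotopy time series
#'
#' Converts to percent signal change by division by the temporal mean,
#' high-pass filters with cutoff `1/(3 * period_s)` Hz, and discards the
#' samples of the first quarter stimulus cycle. The high-pass is a
#' zero-phase DFT-domain filter (frequency bins strictly below the cutoff,
#' including DC, are zeroed), so the gain at the stimulus frequency is
#' exactly 1.
#'
#' @param ts timepoints x vertices matrix (or a vector for one vertex).
#' @param tr_s sampling interval, s.
#' @param period_s stimulus cycle period, s.
#' @return preprocessed matrix with `length - round(period_s/(4 tr_s))` rows.
#' @export
preprocess_timeseries <- function(ts, tr_s, period_s) {
  if (is.vector(ts)) ts <- matrix(ts, ncol = 1)
  nt <- nrow(ts)
  if (nt * tr_s <= 1.25 * period_s)
    stop("time series must cover more than 1.25 stimulus cycles",
         call. = FALSE)
  mu <- colMeans(ts)
  if (any(mu == 0)) stop("zero temporal mean", call. = FALSE)
  psc <- 100 * sweep(ts, 2, mu, "/")

  fc <- 1 / (3 * period_s)
  f <- (seq_len(nt) - 1) / (nt * tr_s)
  f <- pmin(f, 1 / tr_s - f)               # two-sided frequency axis
  Fx <- stats::mvfft(psc)
  Fx[f < fc, ] <- 0
  filt <- Re(stats::mvfft(Fx, inverse = TRUE)) / nt

  drop <- round(period_s / (4 * tr_s))
  out <- filt[(drop + 1):nt, , drop = FALSE]
  # discarding initial samples shifts the time origin; downstream phase
  # estimation must re-reference to the stimulus clock
  attr(out, "t_offset") <- drop * tr_s
  out
}

#' Discrete Fourier coefficient at the stimulus frequency
#'
#' Returns the (unnormalized) DFT coefficient at the frequency bin nearest
#' `stimulus_freq`; with this convention a pure `cos(2 pi f t)` of length N
#' gives amplitude N/2 and phase 0, and `sin` gives phase -pi/2. Coherence
#' is the amplitude at the stimulus bin divided by the total amplitude over
#' all positive-frequency bins.
#'
#' @param ts timepoints x vertices matrix (preprocessed).
#' @param stimulus_freq stimulus frequency, Hz.
#' @param tr_s sampling interval, s.
#' @param t_offset time (s) of the first retained sample relative to the
#'   stimulus clock; defaults to the `t_offset` attribute set by
#'   [preprocess_timeseries()] (0 if absent). Phases are re-referenced to
#'   stimulus time zero.
#' @return list with complex `coef`, `amplitude`, `phase` (radians in
#'   (-pi, pi]), `coherence`, and the selected `bin` (1-based DFT index).
#' @export
fourier_coefficient <- function(ts, stimulus_freq, tr_s,
                                t_offset = attr(ts, "t_offset") %||% 0) {
  if (is.vector(ts)) ts <- matrix(ts, ncol = 1)
  nt <- nrow(ts)
  fs <- 1 / tr_s
  if (stimulus_freq > fs / 2)
    stop("stimulus frequency above Nyquist", call. = FALSE)
  fgrid <- (0:(nt - 1)) * fs / nt
  half <- 2:(floor(nt / 2) + 1)
  k <- half[which.min(abs(fgrid[half] - stimulus_freq))]
  Fx <- stats::mvfft(ts)
  cf <- Fx[k, ] * exp(-2i * pi * fgrid[k] * t_offset)
  amp_all <- colSums(abs(Fx[half, , drop = FALSE]))
  list(coef = cf, amplitude = Mod(cf), phase = wrap_angle(Arg(cf)),
       coherence = ifelse(amp_all > 0, Mod(cf) / amp_all, 0), bin = k)
}

#' Combine Fourier coefficients from opposite stimulus directions
#'
#' The hemodynamic delay adds the same phase lag to runs of either
#' direction while the stimulus phase enters with opposite sign; the
#' reverse-run coefficient is therefore conjugated and complex-averaged
#' with the forward one, which cancels the delay exactly (for delays below
#' a quarter period). The returned phase is the delay-free stimulus phase
#' under the convention of [generate_retino_timeseries()]: a forward-run
#' response `cos(2 pi f t - phase_true - psi)` yields `phase = phase_true`.
#'
#' @param coef_forward,coef_reverse complex coefficients (equal length) at
#'   the same frequency bin.
#' @return object of class `phase_map`: list with `phase` (radians,
#'   (-pi, pi]), `amplitude`, and the complex `coef`.
#' @export
combine_directions <- function(coef_forward, coef_reverse) {
  if (length(coef_forward) != length(coef_reverse))
    stop("mismatched lengths", call. = FALSE)
  comb <- (coef_forward + Conj(coef_reverse)) / 2
  structure(list(phase = wrap_angle(-Arg(comb)), amplitude = Mod(comb),
                 coef = comb), class = "phase_map")
}

#' End-to-end phase map from two opposite-direction runs
#'
#' Convenience wrapper: preprocess both runs, extract the stimulus-frequency
#' coefficient, combine directions.
#'
#' @param ts_forward,ts_reverse timepoints x vertices matrices.
#' @param tr_s sampling interval, s.
#' @param period_s stimulus period, s.
#' @return a `phase_map` (see [combine_directions()]) with `coherence` from
#'   the forward run attached.
#' @export
retino_phase_map <- function(ts_forward, ts_reverse, tr_s, period_s) {
  f <- fourier_coefficient(preprocess_timeseries(ts_forward, tr_s, period_s),
                           1 / period_s, tr_s)
  r <- fourier_coefficient(preprocess_timeseries(ts_reverse, tr_s, period_s),
                           1 / period_s, tr_s)
  pm <- combine_directions(f$coef, r$coef)
  pm$coherence <- f$coherence
  pm
}

#' Foveal exclusion mask from eccentricity phase
#'
#' Retains vertices whose eccentricity phase lies outside the inner
#' `cycle_fraction` (default one-third) of the full phase cycle, measured
#' from the foveal phase origin; used to exclude the foveal confluence where
#' the stripe localizers give no activation.
#'
#' @param eccentricity_phase per-vertex phase in (-pi, pi].
#' @param cycle_fraction excluded fraction of the full cycle, in (0, 1).
#' @param origin foveal phase origin (radians).
#' @return logical mask, `TRUE` = keep.
#' @export
foveal_exclusion_mask <- function(eccentricity_phase, cycle_fraction = 1 / 3,
                                  origin = 0) {
  if (cycle_fraction <= 0 || cycle_fraction >= 1)
    stop("cycle_fraction must lie in (0, 1)", call. = FALSE)
  abs(wrap_angle(eccentricity_phase - origin)) >= pi * cycle_fraction
}
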