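#' Multi-echo dual flip angle FLASH acquisition protocol
#'
#' Defaults reproduce a typical 7 T multi-parameter-mapping protocol:
#' TR = 25 ms per contrast, six equidistant echoes from 2.8 to 16.1 ms, and
#' nominal flip angles of 5 deg (PD-weighted) and 24 deg (T1-weighted).
#'
#' @param tr repetition time in s (recycled to both contrasts).
#' @param te_list echo times in s, strictly increasing.
#' @param nominal_fa nominal flip angles in radians, named `PDw` and `T1w`.
#' @return object of class `flash_protocol`.
#' @export
flash_protocol <- function(tr = 0.025,
                           te_list = seq(0.0028, 0.0161, length.out = 6),
                           nominal_fa = c(PDw = 5 * pi / 180,
                                          T1w = 24 * pi / 180)) {
  if (any(diff(te_list) <= 0)) stop("te_list must be strictly increasing",
                                    call. = FALSE)
  if (any(nominal_fa <= 0) || any(nominal_fa >= pi / 2))
    stop("flip angles must lie in (0, pi/2)", call. = FALSE)
  tr <- rep_len(tr, 2L)
  names(tr) <- names(nominal_fa) <- c("PDw", "T1w")
  if (max(te_list) >= min(tr)) stop("tr must exceed max(te)", call. = FALSE)
  structure(list(tr = tr, te_list = te_list, nominal_fa = nominal_fa),
            class = "flash_protocol")
}

#' Spoiled gradient-echo (FLASH) steady-state signal
#'
#' The exact Ernst-equation signal with mono-exponential effective
#' transverse decay:
#' \deqn{S = A \sin\alpha \frac{1 - E_1}{1 - \cos\alpha \, E_1}
#'       e^{-TE \cdot R_2^*}, \quad E_1 = e^{-TR \cdot R_1}.}
#' Vectorized over locations.
#'
#' @param amplitude_a PD-proportional signal amplitude (arbitrary units).
#' @param r1 longitudinal relaxation rate, s^-1 (>= 0).
#' @param r2s effective transverse relaxation rate, s^-1 (>= 0).
#' @param fa_true achieved flip angle in radians, in (0, pi/2).
#' @param tr,te repetition and echo time in s.
#' @return signal in the units of `amplitude_a`.
#' @export
flash_signal <- function(amplitude_a, r1, r2s, fa_true, tr, te) {
  if (any(fa_true <= 0) || any(fa_true >= pi / 2))
    stop("fa_true must lie in (0, pi/2)", call. = FALSE)
  if (any(r1 < 0) || any(r2s < 0)) stop("r1 and r2s must be >= 0", call. = FALSE)
  e1 <- exp(-tr * r1)
  amplitude_a * sin(fa_true) * (1 - e1) / (1 - cos(fa_true) * e1) *
    exp(-te * r2s)
}

#' ESTATICS fit: joint R2* with per-contrast TE = 0 intercepts
#'
#' Ordinary least squares on log-signals with one shared R2* decay slope
#' across the PDw and T1w contrasts and a separate intercept per contrast
#' (the extrapolation to TE = 0 that removes R2* weighting before the dual
#' flip angle step). One OLS per location, uniform weights.
#'
#' Locations with any non-positive signal cannot be log-transformed; they
#' are flagged invalid (`NA` in all outputs) rather than raising.
#'
#' @param signals numeric array `[contrast, echo, location]` (contrasts
#'   ordered PDw, T1w) or a `multi_echo_signals` object.
#' @param protocol a `flash_protocol`.
#' @return list with `r2s` (s^-1), `s0` (2 x n matrix of TE = 0 intercepts,
#'   rows PDw/T1w), `valid` (logical) and `n_invalid`.
#' @export
estatics_fit <- function(signals, protocol) {
  if (inherits(signals, "multi_echo_signals")) signals <- signals$signal
  d <- dim(signals)
  if (length(d) != 3L || d[1] != 2L)
    stop("signals must be [2 contrasts, echoes, locations]", call. = FALSE)
  ne <- d[2]; n <- d[3]
  if (ne < 2L) stop("need >= 2 echoes per contrast", call. = FALSE)
  te <- protocol$te_list
  if (length(te) != ne) stop("echo count does not match protocol", call. = FALSE)

  # Design: log S_ce = b_c - te_e * r2s; shared slope, 2 intercepts.
  X <- cbind(pdw = rep(c(1, 0), each = ne), t1w = rep(c(0, 1), each = ne),
             negte = -c(te, te))
  P <- solve(crossprod(X), t(X))  # 3 x 2ne projection, reused for all locations

  Y <- matrix(aperm(signals, c(2, 1, 3)), nrow = 2 * ne)  # (echoes within contrast) x n
  valid <- colSums(Y <= 0 | !is.finite(Y)) == 0L
  B <- matrix(NA_real_, 3, n)
  if (any(valid)) B[, valid] <- P %*% log(Y[, valid, drop = FALSE])
  r2s <- B[3, ]
  s0 <- exp(B[1:2, , drop = FALSE])
  rownames(s0) <- c("PDw", "T1w")
  list(r2s = r2s, s0 = s0, valid = valid, n_invalid = sum(!valid))
}

#' Rational dual flip angle R1 and amplitude estimation
#'
#' Implements the small-angle / short-TR rational approximation of the Ernst
#' equation for dual flip angle FLASH data:
#' \deqn{R_1 = \frac{S_{T1}\alpha_{T1}/TR_{T1} - S_{PD}\alpha_{PD}/TR_{PD}}
#'                  {2\,(S_{PD}/\alpha_{PD} - S_{T1}/\alpha_{T1})}}
#' \deqn{A = S_{PD} S_{T1}\,
#'   \frac{TR_{T1}\alpha_{PD}/\alpha_{T1} - TR_{PD}\alpha_{T1}/\alpha_{PD}}
#'        {S_{PD} TR_{T1}\alpha_{PD} - S_{T1} TR_{PD}\alpha_{T1}}}
#' with apparent flip angles corrected by the measured B1+ efficiency
#' (achieved / nominal flip angle) before evaluation.
#'
#' Locations where the denominator is non-positive (non-physical signal
#' ordering, e.g. from noise) are flagged invalid, not raised.
#'
#' @param s0 2 x n matrix of TE = 0 intercepts, rows PDw/T1w (output of
#'   [estatics_fit()]).
#' @param protocol a `flash_protocol`.
#' @param b1_efficiency per-location B1+ efficiency, 1 = nominal (scalar or
#'   length n).
#' @return list with `r1` (s^-1), `amplitude_a`, `valid`, `n_invalid`.
#' @export
dfa_fit <- function(s0, protocol, b1_efficiency = 1) {
  if (is.list(s0) && !is.null(s0$s0)) s0 <- s0$s0
  n <- ncol(s0)
  fT <- rep_len(b1_efficiency, n)
  if (any(fT <= 0)) stop("b1_efficiency must be > 0", call. = FALSE)
  a_pd <- protocol$nominal_fa[["PDw"]] * fT
  a_t1 <- protocol$nominal_fa[["T1w"]] * fT
  tr_pd <- protocol$tr[["PDw"]]; tr_t1 <- protocol$tr[["T1w"]]
  s_pd <- s0["PDw", ]; s_t1 <- s0["T1w", ]

  den <- s_pd / a_pd - s_t1 / a_t1
  valid <- is.finite(den) & den > 0 & is.finite(s_pd) & is.finite(s_t1)
  r1 <- amp <- rep(NA_real_, n)
  r1[valid] <- (s_t1[valid] * a_t1[valid] / tr_t1 -
                s_pd[valid] * a_pd[valid] / tr_pd) / (2 * den[valid])
  amp_den <- s_pd * tr_t1 * a_pd - s_t1 * tr_pd * a_t1
  ok <- valid & is.finite(amp_den) & amp_den != 0
  amp[ok] <- s_pd[ok] * s_t1[ok] *
    (tr_t1 * a_pd[ok] / a_t1[ok] - tr_pd * a_t1[ok] / a_pd[ok]) / amp_den[ok]
  list(r1 = r1, amplitude_a = amp, valid = valid, n_invalid = sum(!valid))
}

#' Calibrate proton density to white matter
#'
#' Scales the PD-proportional amplitude map so that its mean over a white
#' matter mask equals the calibration constant (default 69 percent units).
#' Invariant to global rescaling of the amplitudes.
#'
#' @param amplitude_a amplitude map (arbitrary units).
#' @param wm_mask logical white-matter mask, non-empty.
#' @param calibration_constant target WM mean in pu.
#' @return PD map in percent units.
#' @export
calibrate_pd <- function(amplitude_a, wm_mask, calibration_constant = 69) {
  if (!any(wm_mask)) stop("wm_mask is empty", call. = FALSE)
  m <- mean(amplitude_a[wm_mask], na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("mean amplitude over wm_mask must be > 0",
                                    call. = FALSE)
  amplitude_a * calibration_constant / m
}

#' Macromolecular tissue volume fraction
#'
#' `MTVF = 100 - PD` (percent units); an involution.
#'
#' @param pd PD map in pu.
#' @return MTVF map in pu.
#' @export
mtvf <- function(pd) 100 - pd

#' Full relaxometry fit: signals to quantitative maps
#'
#' Convenience wrapper chaining [estatics_fit()] and [dfa_fit()], optionally
#' followed by [calibrate_pd()] and [mtvf()] when a white-matter mask is
#' given.
#'
#' @inheritParams estatics_fit
#' @inheritParams dfa_fit
#' @param wm_mask optional logical mask for PD calibration.
#' @return list with `r1`, `r2s`, `amplitude_a`, optionally `pd` and `mtvf`,
#'   plus `valid` and `n_invalid`.
#' @export
fit_qmri <- function(signals, protocol, b1_efficiency = 1, wm_mask = NULL) {
  if (inherits(signals, "multi_echo_signals") &&
      !is.null(signals$b1_efficiency) && missing(b1_efficiency))
    b1_efficiency <- signals$b1_efficiency
  est <- estatics_fit(signals, protocol)
  dfa <- dfa_fit(est$s0, protocol, b1_efficiency)
  out <- list(r1 = dfa$r1, r2s = est$r2s, amplitude_a = dfa$amplitude_a,
              valid = est$valid & dfa$valid,
              n_invalid = sum(!(est$valid & dfa$valid)))
  if (!is.null(wm_mask)) {
    out$pd <- calibrate_pd(dfa$amplitude_a, wm_mask)
    out$mtvf <- mtvf(out$pd)
  }
  out
}
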