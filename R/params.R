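# Parameter containers for the two structural hormone models.
#
# Defaults are the published population estimates: they define the stated
# world of the virtual-trial generator and the generating values of every
# recovery experiment.

#' GH population parameters
#'
#' Growth hormone is secreted as a basal rate plus Gaussian pulses; plasma
#' GH is eliminated first order. Drug inhibits pulse mass through an Emax
#' relationship driven from an effect compartment.
#'
#' Defaults (population estimates): baseline 0.056 ng/mL, secretion width
#' 0.184 h, pulse amplitude (mass) 1.69 ng/mL, k_el 3.6 /h, ke0 1.25 /h,
#' Emax -0.648 (64.8% maximal inhibition), EC50 0.609 µg/L, gamma 1 (fixed);
#' variances: omega2 baseline 0.0288, width 0.0434, k_el 0.225, per-pulse
#' amplitude 3.46; between-occasion: width 0.104, k_el 0.00775; proportional
#' residual variance 0.0247.
#'
#' @param baseline steady-state baseline concentration (ng/mL); the basal
#'   secretion rate is `baseline * kel`.
#' @param width Gaussian pulse SD (h).
#' @param amplitude typical pulse mass (ng/mL, time-integrated secretion per
#'   volume).
#' @param kel GH elimination rate (/h).
#' @param ke0 effect-compartment rate (/h).
#' @param emax maximal fractional inhibition of pulse mass, in \[-1, 0\].
#' @param ec50 effect-site concentration at half-maximal inhibition (µg/L).
#' @param gamma Hill coefficient (>= 1; fixed to 1 in the final model).
#' @param omega2 named IIV variances (log scale) for `baseline`, `width`,
#'   `kel`, `amplitude` (the latter acts per pulse).
#' @param bov2 named between-occasion variances for `width`, `kel`.
#' @param sigma2 proportional residual error variance.
#' @return object of class `gh_params`.
#' @export
gh_params <- function(baseline = 0.056, width = 0.184, amplitude = 1.69,
                      kel = 3.6, ke0 = 1.25, emax = -0.648, ec50 = 0.609,
                      gamma = 1,
                      omega2 = c(baseline = 0.0288, width = 0.0434,
                                 kel = 0.225, amplitude = 3.46),
                      bov2 = c(width = 0.104, kel = 0.00775),
                      sigma2 = 0.0247) {
  if (any(c(baseline, width, amplitude, kel, ke0, ec50) <= 0)) {
    stop("gh_params: rates, width, amplitude, baseline, EC50 must be > 0")
  }
  if (emax < -1 || emax > 0) stop("gh_params: emax must lie in [-1, 0]")
  if (gamma < 1) stop("gh_params: gamma must be >= 1")
  if (any(omega2 < 0) || any(bov2 < 0) || sigma2 < 0) {
    stop("gh_params: variances must be >= 0")
  }
  structure(list(baseline = baseline, width = width, amplitude = amplitude,
                 kel = kel, ke0 = ke0, emax = emax, ec50 = ec50,
                 gamma = gamma, omega2 = omega2, bov2 = bov2,
                 sigma2 = sigma2),
            class = "gh_params")
}

#' PRL population parameters
#'
#' Prolactin is released from a precursor pool at rate `kr`, modulated by two
#' circadian cosines (24 h and 12 h periods) and directly inhibited by the
#' drug plasma concentration through an Emax relationship; the pool is
#' replenished at synthesis rate `ks` which declines with cumulative drug
#' exposure through a saturating slope function.
#'
#' Defaults (population estimates): kr 0.011 /h, kel 1.25 /h, ks 13.3
#' ng/mL/h, 24 h cosine amplitude 0.168 / phase 17.3 h, 12 h amplitude
#' 0.095 / phase 10.2 h, Emax -0.91, EC50 1.27 µg/L, slope 2.73 L/(mg·h);
#' IIV variances: ks 0.068, amp24 0.57, amp12 0.87; proportional residual
#' variance 0.049.
#'
#' @param kr pool release rate (/h).
#' @param kel PRL elimination rate (/h).
#' @param ks PRL synthesis rate (ng/mL/h).
#' @param amp24,phase24 24-h cosine amplitude (fraction of mesor) and phase
#'   shift (h, clock-normalised: 0 = 6 a.m.).
#' @param amp12,phase12 12-h cosine amplitude and phase shift (h).
#' @param emax maximal fractional inhibition of the release rate, in
#'   \[-1, 0\].
#' @param ec50 plasma concentration at half-maximal inhibition (µg/L).
#' @param slope steepness of the cumulative-exposure synthesis decline
#'   (L/(mg·h)).
#' @param omega2 named IIV variances for `ks`, `amp24`, `amp12`.
#' @param sigma2 proportional residual error variance.
#' @return object of class `prl_params`.
#' @export
prl_params <- function(kr = 0.011, kel = 1.25, ks = 13.3,
                       amp24 = 0.168, phase24 = 17.3,
                       amp12 = 0.095, phase12 = 10.2,
                       emax = -0.91, ec50 = 1.27, slope = 2.73,
                       omega2 = c(ks = 0.068, amp24 = 0.57, amp12 = 0.87),
                       sigma2 = 0.049) {
  if (any(c(kr, kel, ks, ec50) <= 0)) {
    stop("prl_params: kr, kel, ks, EC50 must be > 0")
  }
  if (abs(amp24) + abs(amp12) >= 1) {
    stop("prl_params: |amp24| + |amp12| must be < 1 so the release rate ",
         "stays positive")
  }
  if (emax < -1 || emax > 0) stop("prl_params: emax must lie in [-1, 0]")
  if (slope < 0) stop("prl_params: slope must be >= 0")
  if (phase24 < 0 || phase24 >= 24 || phase12 < 0 || phase12 >= 24) {
    stop("prl_params: phases must lie in [0, 24)")
  }
  if (any(omega2 < 0) || sigma2 < 0) stop("prl_params: variances must be >= 0")
  structure(list(kr = kr, kel = kel, ks = ks, amp24 = amp24,
                 phase24 = phase24, amp12 = amp12, phase12 = phase12,
                 emax = emax, ec50 = ec50, slope = slope,
                 omega2 = omega2, sigma2 = sigma2),
            class = "prl_params")
}
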