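#' mPTP Ca2+-dependent activation rate
#'
#' Rate of the C0 -> C1 transition of the three-state mPTP chain,
#' `k_c0c1 = alpha0 * (1 + 199 * ca^h / (ca^h + ca0^h))`: equal to `alpha0`
#' at zero mitochondrial Ca2+, `100.5 * alpha0` at the half-max `ca0`, and
#' saturating at `200 * alpha0`.
#'
#' @param params mPTP parameter list, see [default_params()] element `mptp`
#'   (`alpha0` 1/ms, `ca0` uM, `h_mptp`).
#' @param ca_m mitochondrial free Ca2+ (uM), >= 0.
#' @return rate (1/ms).
#' @export
mptp_activation_rate <- function(params, ca_m) {
  if (any(ca_m < 0)) stop("ca_m must be >= 0")
  h <- params$h_mptp
  cah <- ca_m^h
  params$alpha0 * (1 + 199 * cah / (cah + params$ca0^h))
}

#' All four transition rates of the mPTP chain
#'
#' The chain is C0 <-> C1 <-> O. `k_c0c1` is Ca2+-dependent
#' ([mptp_activation_rate()]); `k_c1c0` and `k_oc1` are constant; the
#' opening rate is scaled by the depolarization pre-factor,
#' `k_c1o = alpha_mptp * kc1o0`.
#'
#' @inheritParams mptp_activation_rate
#' @param alpha_mptp dimensionless pre-factor on the C1 -> O rate (>= 0);
#'   1 is control, larger values command higher open probability.
#' @return named list `k_c0c1`, `k_c1c0`, `k_c1o`, `k_oc1` (1/ms).
#' @export
mptp_rates <- function(params, ca_m, alpha_mptp = params$alpha_mptp) {
  if (alpha_mptp < 0) stop("alpha_mptp must be >= 0")
  list(k_c0c1 = mptp_activation_rate(params, ca_m),
       k_c1c0 = params$kc1c0,
       k_c1o  = alpha_mptp * params$kc1o0,
       k_oc1  = params$koc1)
}

#' Stationary open probability of the mPTP chain
#'
#' Exact stationary open probability of the linear three-state chain
#' C0 <-> C1 <-> O:
#' `P_O = kc0c1*kc1o / (kc0c1*kc1o + kc0c1*koc1 + kc1c0*koc1)`.
#' P_O -> 0 as `alpha_mptp -> 0` and P_O -> 1 as `alpha_mptp -> Inf`, and
#' P_O increases with both `alpha_mptp` and `ca_m`.
#'
#' @inheritParams mptp_rates
#' @return open probability in \[0, 1\].
#' @export
mptp_steady_state <- function(params, ca_m, alpha_mptp = params$alpha_mptp) {
  r <- mptp_rates(params, ca_m, alpha_mptp)
  num <- r$k_c0c1 * r$k_c1o
  num / (num + r$k_c0c1 * r$k_oc1 + r$k_c1c0 * r$k_oc1)
}
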