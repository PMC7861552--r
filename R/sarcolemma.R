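#' Names of the sarcolemmal currents in the membrane equation
#'
#' The membrane equation sums exactly these twelve named current densities
#' (plus the stimulus): fast and late Na+, L-type Ca2+, Na+/Ca2+ exchange,
#' inward-rectifier K+, rapid and slow delayed-rectifier K+, fast and slow
#' transient-outward K+, Na+/K+ pump, ATP-sensitive K+, and background Ca2+.
#'
#' @return character vector of the twelve current names.
#' @export
current_names <- function() {
  c("I_Na", "I_NaL", "I_CaL", "I_NCX", "I_K1", "I_Kr", "I_Ks",
    "I_tof", "I_tos", "I_NaK", "I_KATP", "I_Cab")
}

#' Membrane potential time derivative
#'
#' `Cm * dV/dt = sum(currents) - i_sti`. Current entries are stored in the
#' membrane equation's own sign convention (a positive entry depolarizes),
#' so a depolarizing stimulus is a negative `i_sti` (default pulse
#' -80 uA/cm^2): with all ionic currents zero, `i_sti = -80` gives
#' `dV/dt = +80 mV/ms` at `Cm = 1 uF/cm^2`.
#'
#' @param state membrane state list with `V` (mV), `Cm` (uF/cm^2, > 0) and
#'   optionally `gates` (named vector, each in \[0,1\]).
#' @param currents named numeric vector or list with one entry per name in
#'   [current_names()] (uA/cm^2).
#' @param i_sti stimulus current density (uA/cm^2).
#' @return dV/dt (mV/ms).
#' @export
membrane_derivative <- function(state, currents, i_sti = 0) {
  if (is.null(state$Cm) || state$Cm <= 0) stop("Cm must be > 0")
  cur <- unlist(currents)
  missing <- setdiff(current_names(), names(cur))
  if (length(missing))
    stop("missing current entries: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(cur), current_names())
  if (length(extra))
    stop("unknown current entries: ", paste(extra, collapse = ", "))
  (sum(cur) - i_sti) / state$Cm
}

#' Evaluate gate updates and the named sarcolemmal currents
#'
#' Reference (pure R) implementation of the Hodgkin-Huxley-type gate update
#' and current evaluation used inside the compiled core: fast Na+ gates
#' (m, h, j), delayed-rectifier and transient-outward gates updated by the
#' Rush-Larsen exponential scheme, and all twelve named currents evaluated
#' in the membrane equation's sign convention (positive depolarizes).
#' I_KATP grows as cytosolic ATP falls; the L-type current scales with the
#' supplied open-channel fraction (its gating is stochastic and lives per
#' CRU); CaMKII availability of LCCs is applied in the stochastic opening
#' rate, not here.
#'
#' @param state membrane state list: `V` (mV), `Cm`, `gates` (named vector
#'   m, h, j, xr, xs, xtof, ytof, ytos).
#' @param local list of local/whole-cell inputs: `lcc_open_frac` (open LCCs
#'   per CRU divided by channels per CRU), `jncx` (whole-cell NCX Ca2+
#'   extrusion flux, uM/ms), `atp` (mM).
#' @param dt time step (ms); gates advance by one step.
#' @param params full parameter list (element `membrane` is used).
#' @return list with `state` (gates advanced) and `currents` (named vector
#'   over [current_names()], uA/cm^2).
#' @export
evolve_currents <- function(state, local, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  p <- params$membrane
  V <- state$V
  g <- state$gates

  rl <- function(g0, inf, tau) inf + (g0 - inf) * exp(-dt / tau)
  dv <- V + 47.13
  am <- if (abs(dv) < 1e-6) 3.2 else 0.32 * dv / (1 - exp(-0.1 * dv))
  bm <- 0.08 * exp(-V / 11)
  if (V < -40) {
    ah <- 0.135 * exp(-(80 + V) / 6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  } else {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  }
  g["m"] <- rl(g["m"], am / (am + bm), 1 / (am + bm))
  g["h"] <- rl(g["h"], ah / (ah + bh), 1 / (ah + bh))
  g["j"] <- rl(g["j"], aj / (aj + bj), 1 / (aj + bj))
  g["xr"] <- rl(g["xr"], 1 / (1 + exp(-(V + 21.5) / 7.5)), p$tau_xr)
  g["xs"] <- rl(g["xs"], 1 / (1 + exp(-(V - 1.5) / 16.7)), p$tau_xs)
  g["xtof"] <- rl(g["xtof"], 1 / (1 + exp(-(V + 3) / 15)), p$tau_xtof)
  yinf <- 1 / (1 + exp((V + 33.5) / 10))
  g["ytof"] <- rl(g["ytof"], yinf, p$tau_ytof)
  g["ytos"] <- rl(g["ytos"], yinf, p$tau_ytos)
  if (any(g < -1e-9 | g > 1 + 1e-9))
    stop("gating variable escaped [0,1]; numerical instability, reduce dt")
  g <- pmin(pmax(g, 0), 1)

  conv <- stats::setNames(numeric(12), current_names())
  conv[["I_Na"]] <- p$g_na * g[["m"]]^3 * g[["h"]] * g[["j"]] * (V - p$e_na)
  conv[["I_NaL"]] <- p$g_nal / (1 + exp(-(V + 47.1) / 3)) * (V - p$e_na)
  conv[["I_CaL"]] <- params$lcc$g_cur * local$lcc_open_frac * (V - p$e_ca)
  conv[["I_NCX"]] <- -p$c_ncx * local$jncx
  ak1 <- 1.02 / (1 + exp(0.2385 * (V - p$e_k - 59.215)))
  bk1 <- (0.49124 * exp(0.08032 * (V - p$e_k + 5.476)) +
            exp(0.06175 * (V - p$e_k - 594.31))) /
    (1 + exp(-0.5143 * (V - p$e_k + 4.753)))
  conv[["I_K1"]] <- p$g_k1 * ak1 / (ak1 + bk1) * (V - p$e_k)
  conv[["I_Kr"]] <- p$g_kr * g[["xr"]] / (1 + exp((V + 9) / 22.4)) * (V - p$e_k)
  conv[["I_Ks"]] <- p$g_ks * g[["xs"]]^2 * (V - p$e_k)
  conv[["I_tof"]] <- p$g_tof * g[["xtof"]] * g[["ytof"]] * (V - p$e_k)
  conv[["I_tos"]] <- p$g_tos * g[["xtof"]] * g[["ytos"]] * (V - p$e_k)
  conv[["I_NaK"]] <- p$g_nak / (1 + exp(-(V + 60) / 40))
  conv[["I_KATP"]] <- p$g_katp / (1 + (local$atp / p$katp_km)^2) * (V - p$e_k)
  conv[["I_Cab"]] <- p$g_cab * (V - p$e_ca)
  # conventional (outward-positive) -> membrane-equation convention
  currents <- -conv
  names(currents) <- current_names()

  state$gates <- g
  list(state = state, currents = currents)
}

#' Pacing stimulus waveform
#'
#' Rectangular current pulse delivered periodically: `amplitude` during
#' `[k * period, k * period + duration)` for every integer beat k >= 0,
#' zero otherwise. Defaults: -80 uA/cm^2 for 0.5 ms.
#'
#' @param spec list with `amplitude` (uA/cm^2), `duration` (ms, > 0) and
#'   `period` (pacing cycle length PCL, ms, > duration).
#' @param t time (ms), >= 0; vectorized.
#' @return stimulus current density at `t` (uA/cm^2).
#' @export
stimulus_waveform <- function(spec, t) {
  if (spec$duration <= 0) stop("stimulus duration must be > 0")
  if (spec$period <= spec$duration) stop("PCL must exceed stimulus duration")
  if (any(t < 0)) stop("t must be >= 0")
  phase <- t %% spec$period
  ifelse(phase < spec$duration, spec$amplitude, 0)
}
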