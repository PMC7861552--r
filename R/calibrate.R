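#' Calibrate the slow CaMKII law to its kinetic anchors
#'
#' The oxidized-CaMKII activation law has three free rate constants
#' (`camkii_k0`, `camkii_kauto`, `camkii_koff`). This routine fits them so
#' that, given the control and depolarized drives (the Ca2+/ROS drive
#' [camkii_drive()] evaluated at the paced steady states of the fast
#' subsystem), the law satisfies three anchors simultaneously: (i) resting
#' activation `a_rest` is a steady state under the control drive, (ii)
#' activation reaches `a_30s` after 30 s under the depolarized drive, and
#' (iii) activation reaches `a_1000s` after 1000 s under the depolarized
#' drive. A single-exponential law cannot satisfy these jointly (the
#' 1000 s / 30 s response ratio exceeds the linear-regime bound), which is
#' why the law is autocatalytic; the fit is a straightforward least-squares
#' solve in log-parameter space.
#'
#' @param params full parameter list.
#' @param u_ctrl drive value under paced control conditions.
#' @param u_dep drive value under paced mitochondrial depolarization.
#' @param a_rest,a_30s,a_1000s activation anchors (fractions; defaults
#'   0.004, 0.012, 0.74).
#' @return `params` with the three CaMKII constants replaced by the fitted
#'   values (and the fit diagnostics in attribute `"fit"`).
#' @export
calibrate_slow_signaling <- function(params, u_ctrl, u_dep,
                                     a_rest = 0.004, a_30s = 0.012,
                                     a_1000s = 0.74) {
  sg <- params$signaling
  amax <- sg$camkii_amax
  integrate_a <- function(k0, kauto, koff, u, a0, t_s, dt_s = 0.2) {
    a <- a0
    out <- c()
    keep <- sort(unique(t_s))
    nt <- ceiling(max(keep) / dt_s)
    for (i in seq_len(nt)) {
      da <- u * (k0 + kauto * a) * (1 - a / amax) - koff * a
      a <- min(max(a + dt_s * 1000 * da, 0), amax)  # rates are per ms
      tcur <- i * dt_s
      if (any(abs(tcur - keep) < dt_s / 2))
        out <- c(out, a)
    }
    out
  }
  obj <- function(lp) {
    k0 <- exp(lp[1]); kauto <- exp(lp[2]); koff <- exp(lp[3])
    # anchor (i): control steady state at a_rest
    da0 <- u_ctrl * (k0 + kauto * a_rest) * (1 - a_rest / amax) - koff * a_rest
    aa <- integrate_a(k0, kauto, koff, u_dep, a_rest, c(30, 1000))
    (da0 / (koff * a_rest + 1e-15))^2 +
      (log(aa[1] / a_30s))^2 + (log(aa[2] / a_1000s))^2
  }
  # analytic starting point from the linearized growth analysis
  eps <- 1 - a_1000s / amax
  r_guess <- log(a_30s / a_rest) / 30          # 1/s
  koff0 <- r_guess * eps / (1 - eps)
  kauto0 <- koff0 / (eps * u_dep)
  k00 <- a_rest * (koff0 - u_ctrl * kauto0) / u_ctrl
  if (!is.finite(k00) || k00 <= 0) k00 <- 1e-3 * koff0
  start <- log(c(k00, kauto0, koff0) / 1000)   # per-ms units
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  k <- exp(fit$par)
  params$signaling$camkii_k0 <- k[1]
  params$signaling$camkii_kauto <- k[2]
  params$signaling$camkii_koff <- k[3]
  attr(params, "fit") <- fit
  params
}
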