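# Shared fixtures: parameter sets and small deterministic helpers used
# across the suite. Everything is built in code; no data files.

small_params <- function(...) {
  p <- default_params("small")
  ov <- list(...)
  if (length(ov)) p <- modify_params(p, ov)
  p
}

# Brute-force stationary distribution of the 3-state mPTP chain C0<->C1<->O:
# solve pi Q = 0 with sum(pi) = 1 by linear algebra, independently of the
# closed form in the package.
mptp_stationary_numeric <- function(k_c0c1, k_c1c0, k_c1o, k_oc1) {
  sc <- max(k_c0c1, k_c1c0, k_c1o, k_oc1)  # scale for conditioning
  Q <- matrix(c(-k_c0c1, k_c0c1, 0,
                k_c1c0, -(k_c1c0 + k_c1o), k_c1o,
                0, k_oc1, -k_oc1), nrow = 3, byrow = TRUE) / sc
  A <- rbind(t(Q), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi <- qr.solve(A, b)
  pi[3]
}

# Closed-form stationary open fraction of the three-state RyR cycle
# closed -> open (kon) -> refractory (koff) -> closed (krec).
cycle_open_frac <- function(kon, koff, krec) {
  (1 / koff) / (1 / kon + 1 / koff + 1 / krec)
}

expect_snapshot_equal <- function(a, b) {
  for (nm in c("t", "V", "gates", "ca_p", "ca_s", "ca_i", "ca_nsr", "ca_jsr",
               "ros", "ryr_open", "lcc_open", "ca_m", "dpsi", "mptp_state",
               "camkii_act", "atp", "rng_state")) {
    expect_identical(a[[nm]], b[[nm]], label = paste("snapshot field", nm))
  }
}
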