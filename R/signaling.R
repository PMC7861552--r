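#' Cytosolic ROS field: one explicit-Euler step
#'
#' Per-CRU ROS gains local mitochondrial emission, decays by first-order
#' scavenging toward zero, and diffuses to face-adjacent CRUs. With every
#' mitochondrion polarized (baseline emission `k_scav * ros_base`) the field
#' rests at `ros_base` (default 0.1 uM); a uniform elevated emission `e`
#' settles at `e / k_scav`.
#'
#' This is the reference (pure R) implementation of the update also applied
#' inside the compiled simulation core.
#'
#' @param grid `spatial_grid` from [build_lattice()].
#' @param ros numeric vector, per-CRU ROS (uM).
#' @param emission numeric vector, per-CRU emission rate (uM/ms).
#' @param params signaling parameter list (`k_scav` 1/ms, `d_ros` 1/ms).
#' @param dt time step (ms).
#' @return updated ROS vector.
#' @export
ros_field_step <- function(grid, ros, emission, params, dt) {
  stopifnot(length(ros) == grid$cru_count, length(emission) == grid$cru_count)
  lap <- vapply(seq_len(grid$cru_count), function(i) {
    sum(ros[grid$cru_neighbors[[i]]] - ros[i])
  }, numeric(1))
  pmax(0, ros + dt * (emission - params$k_scav * ros + params$d_ros * lap))
}

#' CaMKII activation drive
#'
#' Saturating (Hill-2) drive of CaMKII activation by cytosolic Ca2+
#' (Ca2+/calmodulin arm) and by ROS (oxidized arm):
#' `u = w_ca * ca^2/(ca^2 + km_ca^2) + w_ros * ros^2/(ros^2 + km_ros^2)`.
#'
#' @param params signaling parameter list (`camkii_w_ca`, `camkii_km_ca` uM,
#'   `camkii_w_ros`, `camkii_km_ros` uM).
#' @param ca_cyt whole-cell averaged cytosolic Ca2+ (uM).
#' @param ros_cyt whole-cell averaged cytosolic ROS (uM).
#' @return dimensionless drive >= 0.
#' @export
camkii_drive <- function(params, ca_cyt, ros_cyt) {
  params$camkii_w_ca * ca_cyt^2 / (ca_cyt^2 + params$camkii_km_ca^2) +
    params$camkii_w_ros * ros_cyt^2 / (ros_cyt^2 + params$camkii_km_ros^2)
}

#' Time derivative of CaMKII activation
#'
#' Autocatalytic (subunit-to-subunit autophosphorylation) activation with
#' slow decay:
#' `da/dt = u * (k0 + k_auto * a) * (1 - a/a_max) - k_off * a`,
#' where `u` is the Ca2+/ROS drive from [camkii_drive()]. The autocatalytic
#' term makes activation kinetics strongly drive-dependent: at the control
#' drive activation rests near its floor (~0.4%), while under sustained
#' mitochondrial depolarization it grows slowly (roughly tripling over 30 s)
#' yet ultimately approaches a high quasi-steady level over ~1000 s.
#'
#' @param params signaling parameter list (`camkii_k0`, `camkii_kauto`,
#'   `camkii_koff` in 1/ms, `camkii_amax` fraction).
#' @param camkii_act activation fraction in \[0, 1\].
#' @param ca_cyt,ros_cyt drives (uM).
#' @return da/dt (fraction/ms).
#' @export
camkii_derivative <- function(params, camkii_act, ca_cyt, ros_cyt) {
  u <- camkii_drive(params, ca_cyt, ros_cyt)
  u * (params$camkii_k0 + params$camkii_kauto * camkii_act) *
    (1 - camkii_act / params$camkii_amax) - params$camkii_koff * camkii_act
}

#' Time derivative of cytosolic ATP
#'
#' Whole-cell ATP relaxes toward a production-set target:
#' `datp/dt = (atp_inf(f) - atp) / tau_atp`, with
#' `atp_inf(f) = max(atp_min, atp_max - atp_drop * (1 - f)^atp_pow)` where `f` is
#' the fraction of mitochondria currently producing ATP (polarized). ADP
#' mirrors ATP against the fixed adenine pool. The time constant is slow:
#' 30 s of ~30% depolarization changes ATP only slightly, while the ~1000-s
#' quasi-steady level falls toward `atp_inf`.
#'
#' @param params signaling parameter list (`atp_max`, `atp_min`, `atp_drop`
#'   mM, `tau_atp` ms).
#' @param atp cytosolic ATP (mM).
#' @param fraction_producing fraction of polarized (ATP-producing)
#'   mitochondria, in \[0, 1\].
#' @return dATP/dt (mM/ms).
#' @export
atp_derivative <- function(params, atp, fraction_producing) {
  if (any(fraction_producing < 0 | fraction_producing > 1))
    stop("fraction_producing must be in [0,1]")
  target <- pmax(params$atp_min,
                 params$atp_max -
                   params$atp_drop * (1 - fraction_producing)^params$atp_pow)
  (target - atp) / params$tau_atp
}

#' Fast-forward integration of the slow variables
#'
#' CaMKII activation and cytosolic ATP evolve orders of magnitude more
#' slowly than Ca2+ cycling (quasi-steady-state premise). This mode
#' integrates only the two slow ODEs against a frozen description of the
#' paced periodic steady state of the fast subsystem (its time-averaged
#' cytosolic Ca2+ and ROS and the fraction of producing mitochondria),
#' reaching 1000-s horizons at negligible cost.
#'
#' @param params full parameter list from [default_params()] (element
#'   `signaling` is used).
#' @param drives list with `ca_cyt` (uM), `ros_cyt` (uM),
#'   `fraction_producing` in \[0,1\] — the paced-steady-state averages, e.g.
#'   measured from a [run_simulation()] trace.
#' @param duration_s horizon in seconds (default 1000).
#' @param camkii0,atp0 initial values (defaults: resting activation and ATP).
#' @param dt_s integration step in seconds (default 0.05).
#' @return data.frame with columns `t_s`, `camkii_act`, `atp`, `adp`.
#' @export
fast_forward_slow <- function(params, drives, duration_s = 1000,
                              camkii0 = params$signaling$camkii_rest,
                              atp0 = params$signaling$atp_rest,
                              dt_s = 0.05) {
  sg <- params$signaling
  nt <- ceiling(duration_s / dt_s)
  keep <- unique(c(seq(0, nt, by = max(1L, floor(nt / 2000))), nt))
  a <- camkii0
  atp <- atp0
  dt_ms <- dt_s * 1000
  out_t <- numeric(0); out_a <- numeric(0); out_atp <- numeric(0)
  for (k in 0:nt) {
    if (k %in% keep) {
      out_t <- c(out_t, k * dt_s); out_a <- c(out_a, a); out_atp <- c(out_atp, atp)
    }
    if (k == nt) break
    a <- a + dt_ms * camkii_derivative(sg, a, drives$ca_cyt, drives$ros_cyt)
    a <- min(max(a, 0), sg$camkii_amax)
    atp <- atp + dt_ms * atp_derivative(sg, atp, drives$fraction_producing)
    atp <- min(max(atp, sg$atp_min), sg$atp_pool)
  }
  data.frame(t_s = out_t, camkii_act = out_a, atp = out_atp,
             adp = sg$atp_pool - out_atp)
}

#' Validate and normalize a clamp list
#'
#' Clamps hold a chosen model variable at a fixed value from a start time
#' on: after every integration step the target is overwritten with the clamp
#' value, leaving all other dynamics untouched. `mptp_closed` commands every
#' mPTP to its deep closed state C0 (its `value` is ignored).
#'
#' @param clamps list of clamp specs, each a list with `target` (one of
#'   `ros_cyt`, `camkii_act`, `atp_cyt`, `ca_mito`, `ca_cyt`,
#'   `mptp_closed`), `value`, and optional `start_time` (ms, default 0).
#' @return normalized list (targets validated, start times filled in).
#' @export
validate_clamps <- function(clamps) {
  if (is.null(clamps) || length(clamps) == 0) return(list())
  targets_ok <- c("ros_cyt", "camkii_act", "atp_cyt", "ca_mito", "ca_cyt",
                  "mptp_closed")
  out <- lapply(clamps, function(cl) {
    if (is.null(cl$target) || !cl$target %in% targets_ok)
      stop("unknown clamp target: ", cl$target)
    if (is.null(cl$start_time)) cl$start_time <- 0
    if (is.null(cl$value)) cl$value <- 0
    rng <- switch(cl$target,
                  camkii_act = c(0, 1),
                  c(0, Inf))
    if (cl$target != "mptp_closed" &&
        (cl$value < rng[1] || cl$value > rng[2]))
      stop(sprintf("clamp value %g outside physical range for %s",
                   cl$value, cl$target))
    cl
  })
  tg <- vapply(out, `[[`, "", "target")
  if (anyDuplicated(tg))
    stop("conflicting clamps: target(s) ",
         paste(unique(tg[duplicated(tg)]), collapse = ", "),
         " clamped more than once")
  out
}

#' Apply clamps to a model state
#'
#' Reference implementation of the clamp semantics on a snapshot/state list
#' (the compiled core enforces the same rule after every step): for each
#' clamp whose `start_time` has passed, overwrite the target variable.
#'
#' @param state model state list (fields as in the snapshot returned by
#'   [run_simulation()]).
#' @param clamps clamp list, see [validate_clamps()].
#' @param t current time (ms).
#' @return state with clamps applied.
#' @export
apply_clamps <- function(state, clamps, t) {
  clamps <- validate_clamps(clamps)
  for (cl in clamps) {
    if (t < cl$start_time) next
    state <- switch(cl$target,
      ros_cyt = { state$ros[] <- cl$value; state },
      camkii_act = { state$camkii_act <- cl$value; state },
      atp_cyt = { state$atp <- cl$value; state },
      ca_mito = { state$ca_m[] <- cl$value; state },
      ca_cyt = { state$ca_i[] <- cl$value; state },
      mptp_closed = { state$mptp_state[] <- 0L; state }
    )
  }
  state
}
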