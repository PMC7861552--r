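#' Define a simulation protocol
#'
#' A protocol bundles the pacing and intervention settings of one run:
#' pacing cycle length, total duration, the mPTP and MCU pre-factors, the
#' redox-arm switches used to dissect the ROS mechanism, and any clamps.
#'
#' @param pcl pacing cycle length (ms).
#' @param duration total simulated time (ms); 30 s runs are the standard
#'   free-running protocol.
#' @param alpha_mptp pre-factor on the C1 -> O mPTP rate (1 = control).
#' @param alpha_mcu pre-factor on the maximal MCU conductance (1 = control).
#' @param mncx_scale scale on mitochondrial NCX efflux (1 = control).
#' @param stim_on deliver the pacing stimulus (TRUE) or leave the cell
#'   quiescent.
#' @param ryr_redox_off disable the redox effect of ROS on RyRs
#'   (sets the ROS-dependent rate increment to zero).
#' @param serca_redox_off disable the redox effect of ROS on SERCA
#'   (forces the redox uptake factor to 1).
#' @param sarco_open keep sarcolemmal Ca2+ fluxes (LCC influx, NCX
#'   extrusion, background influx) and the stimulus enabled; FALSE gives a
#'   closed cell for conservation audits.
#' @param mito_on enable mitochondrial Ca2+ fluxes (MCU, mNCX, mPTP efflux).
#' @param clamps list of clamp specs, see [validate_clamps()].
#' @return a `protocol` list.
#' @export
protocol_spec <- function(pcl = 500, duration = 30000, alpha_mptp = 1,
                          alpha_mcu = 1, mncx_scale = 1, stim_on = TRUE,
                          ryr_redox_off = FALSE, serca_redox_off = FALSE,
                          sarco_open = TRUE, mito_on = TRUE, clamps = list()) {
  clamps <- validate_clamps(clamps)
  structure(list(pcl = pcl, duration = duration, alpha_mptp = alpha_mptp,
                 alpha_mcu = alpha_mcu, mncx_scale = mncx_scale,
                 stim_on = stim_on, ryr_redox_off = ryr_redox_off,
                 serca_redox_off = serca_redox_off, sarco_open = sarco_open,
                 mito_on = mito_on, clamps = clamps),
            class = "protocol")
}

clamp_code <- function(target) {
  match(target, c("ros_cyt", "camkii_act", "atp_cyt", "ca_mito", "ca_cyt",
                  "mptp_closed"))
}

geom_for_cpp <- function(grid) {
  nbr <- matrix(-1L, nrow = grid$cru_count, ncol = 6L)
  for (i in seq_len(grid$cru_count)) {
    v <- grid$cru_neighbors[[i]] - 1L
    if (length(v)) nbr[i, seq_along(v)] <- v
  }
  list(cru_count = grid$cru_count, mito_count = grid$mito_count,
       nbr = nbr, mito_of = grid$mito_of_cru - 1L)
}

protocol_for_cpp <- function(protocol) {
  cl <- protocol$clamps
  list(pcl = protocol$pcl, duration = protocol$duration,
       stim_on = protocol$stim_on, alpha_mptp = protocol$alpha_mptp,
       alpha_mcu = protocol$alpha_mcu, mncx_scale = protocol$mncx_scale,
       ryr_redox_off = protocol$ryr_redox_off,
       serca_redox_off = protocol$serca_redox_off,
       sarco_open = protocol$sarco_open, mito_on = protocol$mito_on,
       clamp_target = vapply(cl, function(x) clamp_code(x$target), 1L),
       clamp_value = vapply(cl, function(x) as.numeric(x$value), 1.0),
       clamp_start = vapply(cl, function(x) as.numeric(x$start_time), 1.0))
}

trace_colnames <- function() {
  c("t", "V", "ca_i", "ca_s", "ca_jsr", "ca_nsr", "ca_m", "p_mptp", "dpsi",
    "ros", "camkii_act", "atp", "j_up", "j_rel", "dt_small", "f_producing",
    "i_sti")
}

#' Run a paced (or clamped) whole-cell simulation
#'
#' Advances the full stochastic model — membrane potential, per-CRU Ca2+
#' cycling with Markov RyR/LCC gating, per-mitochondrion Ca2+/mPTP/membrane
#' potential, the cytosolic ROS field, and the slow CaMKII/ATP variables —
#' for the protocol's duration, using explicit Euler with a global adaptive
#' step (`dt_upstroke` while `|dV/dt|` exceeds the upstroke criterion, else
#' `dt_normal`). Whole-cell averages are emitted every `output_interval` ms.
#'
#' A given `(seed, params, protocol)` triple fully determines every output;
#' re-running reproduces the trajectory bit for bit. Passing the returned
#' `snapshot` back as `init_state` resumes the run mid-stream with identical
#' continuation.
#'
#' @param params parameter list from [default_params()].
#' @param protocol a [protocol_spec()].
#' @param seed integer master seed; per-site streams are derived from it.
#' @param init_state optional snapshot from a previous run (warm start).
#' @param grid optional prebuilt [build_lattice()] grid (rebuilt from
#'   `params$geometry` when omitted).
#' @return list with `trace` (data.frame of whole-cell averages per output
#'   interval: voltage, compartment Ca2+, mPTP open fraction, mitochondrial
#'   potential, ROS, CaMKII, ATP, uptake/release fluxes, step-size flag),
#'   `snapshot` (complete final state including RNG streams), `steps`
#'   (steps taken), `grid`, `protocol`, `seed`.
#' @export
run_simulation <- function(params, protocol, seed = 1, init_state = NULL,
                           grid = NULL) {
  stopifnot(inherits(protocol, "protocol"))
  if (is.null(grid))
    grid <- build_lattice(params$geometry$cru_dims, params$geometry$mito_dims)
  if (params$lcc$n_lcc >= 64L) stop("n_lcc must be < 64")
  if (protocol$duration < 0) stop("duration must be >= 0")
  if (protocol$duration == 0) {
    res <- .sim_run_cpp(params, geom_for_cpp(grid),
                        protocol_for_cpp(modifyList(protocol,
                                                    list(duration = 0))),
                        as.numeric(seed), init_state, FALSE)
    tr <- as.data.frame(matrix(numeric(0), ncol = 17))
    names(tr) <- trace_colnames()
    return(list(trace = tr, snapshot = res$snapshot, steps = 0,
                grid = grid, protocol = protocol, seed = seed))
  }
  res <- .sim_run_cpp(params, geom_for_cpp(grid), protocol_for_cpp(protocol),
                      as.numeric(seed), init_state, TRUE)
  tr <- as.data.frame(res$trace)
  names(tr) <- trace_colnames()
  list(trace = tr, snapshot = res$snapshot, steps = res$steps,
       grid = grid, protocol = protocol, seed = seed)
}

#' Advance the model by a single time step
#'
#' One step of the hybrid scheme: the step size is chosen by the upstroke
#' criterion, all stochastic channels (LCC, RyR, mPTP) take one sampling
#' step, all continuous variables one Euler step, and clamps are applied.
#' Implemented as a duration-one-step call of the compiled core so that
#' stepping N times equals one N-step run exactly.
#'
#' @param params parameter list.
#' @param protocol a [protocol_spec()].
#' @param state snapshot to advance (NULL = fresh initial state).
#' @param seed master seed (only meaningful on the first step; thereafter
#'   RNG streams continue from the snapshot).
#' @return list as in [run_simulation()] whose `snapshot` is the advanced
#'   state.
#' @export
advance_step <- function(params, protocol, state = NULL, seed = 1) {
  dt <- params$engine$dt_normal
  if (!is.null(state) && abs(state$dvdt) > params$engine$upstroke_dvdt)
    dt <- params$engine$dt_upstroke
  p1 <- protocol
  p1$duration <- dt
  if (!is.null(state)) p1$duration <- dt
  run_simulation(params, p1, seed = seed, init_state = state)
}
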