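#' RyR close-to-open rate
#'
#' Closed-to-open transition rate of the RyR cluster,
#' `k12 = k_base * k_u * (1 + dk_camkii + dk_ros) * ca_dyad^2`, where the two
#' dimensionless increments carry the CaMKII and redox (ROS) enhancement of
#' RyR opening. `k_base * k_u` is kept as one calibrated composite rate
#' constant (units 1/(uM^2 ms)).
#'
#' @param params RyR parameter list, see [default_params()] element `ryr`
#'   (uses `k_base_ku`).
#' @param ca_dyad dyadic-space Ca2+ concentration (uM), >= 0.
#' @param dk_camkii CaMKII-dependent increment from [delta_k_camkii()], >= 0.
#' @param dk_ros ROS-dependent increment from [delta_k_ros()], >= 0.
#' @return transition rate (1/ms).
#' @export
ryr_rate_k12 <- function(params, ca_dyad, dk_camkii = 0, dk_ros = 0) {
  if (any(ca_dyad < 0)) stop("ca_dyad must be >= 0")
  if (any(dk_camkii < 0) || any(dk_ros < 0)) stop("rate increments must be >= 0")
  params$k_base_ku * (1 + dk_camkii + dk_ros) * ca_dyad^2
}

#' CaMKII-dependent RyR rate increment
#'
#' Hill-saturating increment
#' `dk = dk_camk_max / (1 + (km_cam_ryr / camkii_act)^h_cam_ryr)`, with the
#' defined limit 0 as activation goes to 0.
#'
#' @param params RyR parameter list (`dk_camk_max`, `km_cam_ryr`, `h_cam_ryr`).
#' @param camkii_act CaMKII activation fraction in \[0, 1\].
#' @return dimensionless increment in \[0, `dk_camk_max`).
#' @export
delta_k_camkii <- function(params, camkii_act) {
  if (any(camkii_act < 0 | camkii_act > 1)) stop("camkii_act must be in [0,1]")
  out <- ifelse(camkii_act <= 0, 0,
                params$dk_camk_max /
                  (1 + (params$km_cam_ryr / camkii_act)^params$h_cam_ryr))
  as.numeric(out)
}

#' ROS-dependent RyR rate increment
#'
#' Hill-saturating increment
#' `dk = dk_ros_max / (1 + (km_ros_ryr / ros_cyt)^h_ros_ryr)`; limit 0 as ROS
#' goes to 0 and `dk_ros_max` as ROS grows. Setting `dk_ros_max = 0` disables
#' the redox effect on RyRs entirely.
#'
#' @param params RyR parameter list (`dk_ros_max`, `km_ros_ryr`, `h_ros_ryr`).
#' @param ros_cyt cytosolic ROS concentration (uM), >= 0.
#' @return dimensionless increment in \[0, `dk_ros_max`).
#' @export
delta_k_ros <- function(params, ros_cyt) {
  if (any(ros_cyt < 0)) stop("ros_cyt must be >= 0")
  out <- ifelse(ros_cyt <= 0, 0,
                params$dk_ros_max /
                  (1 + (params$km_ros_ryr / ros_cyt)^params$h_ros_ryr))
  as.numeric(out)
}

#' ATP/ADP dependence of SERCA
#'
#' Cortassa-type factor
#' `f = 1 / (1 + adp/ki_up_prime + (1 + adp/ki_up) * km_up_atp / atp)`.
#' Falls as ATP falls or ADP accumulates; 1 in the ATP-saturated, ADP-free
#' limit.
#'
#' @param params SERCA parameter list (`km_up_atp`, `ki_up`, `ki_up_prime`,
#'   all mM).
#' @param atp cytosolic ATP (mM), > 0.
#' @param adp cytosolic ADP (mM), >= 0.
#' @return factor in (0, 1\].
#' @export
serca_atp_factor <- function(params, atp, adp) {
  if (any(atp <= 0)) stop("atp must be > 0 (factor undefined at atp = 0)")
  if (any(adp < 0)) stop("adp must be >= 0")
  1 / (1 + adp / params$ki_up_prime +
         (1 + adp / params$ki_up) * params$km_up_atp / atp)
}

#' Redox dependence of SERCA
#'
#' `f = 1/(1 + (ros/kd_ros)^h) + 0.75/(1 + (kd_ros/ros)^h)`: a smooth
#' crossover from 1 (reduced, low-ROS limit) to 0.75 (oxidized limit), equal
#' to 0.875 at `ros = kd_ros`. Overriding this factor to constant 1 disables
#' the redox effect on SERCA.
#'
#' @param params SERCA parameter list (`kd_ros` in uM, `h_ros_serca`).
#' @param ros_cyt cytosolic ROS concentration (uM), >= 0.
#' @return factor in (0.75, 1\].
#' @export
serca_ros_factor <- function(params, ros_cyt) {
  if (any(ros_cyt < 0)) stop("ros_cyt must be >= 0")
  h <- params$h_ros_serca
  kd <- params$kd_ros
  out <- ifelse(ros_cyt <= 0, 1,
                1 / (1 + (ros_cyt / kd)^h) + 0.75 / (1 + (kd / ros_cyt)^h))
  as.numeric(out)
}

#' CaMKII (phospholamban) reduction of the SERCA half-max
#'
#' CaMKII phosphorylation of phospholamban relieves SERCA inhibition, which
#' is modeled as a saturating reduction of the half-maximal Ca2+ value:
#' `plb = plb_max * act^h / (act^h + plb_km^h)`. The effective half-max is
#' `k_i - plb` and must stay positive for all activations in \[0, 1\].
#'
#' @param params SERCA parameter list (`plb_max` uM, `plb_km`, `plb_h`).
#' @param camkii_act activation fraction in \[0, 1\].
#' @return half-max reduction (uM).
#' @export
plb_shift <- function(params, camkii_act) {
  if (any(camkii_act < 0 | camkii_act > 1)) stop("camkii_act must be in [0,1]")
  a <- camkii_act^params$plb_h
  params$plb_max * a / (a + params$plb_km^params$plb_h)
}

#' SERCA uptake flux
#'
#' `J_up = v_up * f_atp * f_ros * ca^2 / (ca^2 + (k_i - plb(camkii))^2)`:
#' Hill-2 uptake with maximal strength `v_up`, multiplicatively modulated by
#' the ATP/ADP and redox factors, and a CaMKII-dependent (phospholamban)
#' reduction of the half-max so higher CaMKII activation increases uptake.
#'
#' @param params SERCA parameter list (`v_up` uM/ms, `k_i` uM, plus
#'   phospholamban constants used by [plb_shift()]).
#' @param ca_cyt local cytosolic Ca2+ (uM), >= 0.
#' @param camkii_act CaMKII activation fraction in \[0, 1\].
#' @param f_atp ATP factor from [serca_atp_factor()].
#' @param f_ros redox factor from [serca_ros_factor()].
#' @return uptake flux (uM/ms).
#' @export
serca_flux <- function(params, ca_cyt, camkii_act, f_atp = 1, f_ros = 1) {
  if (any(ca_cyt < 0)) stop("ca_cyt must be >= 0")
  khalf <- params$k_i - plb_shift(params, camkii_act)
  if (any(khalf <= 0))
    stop("effective SERCA half-max k_i - plb(camkii) must stay > 0; check plb_max < k_i")
  ca2 <- ca_cyt^2
  params$v_up * f_atp * f_ros * ca2 / (ca2 + khalf^2)
}
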