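#' Default model parameters
#'
#' Returns the complete nested parameter list for the coupled CRU /
#' mitochondrion myocyte model. The `"reduced"` preset (16 x 8 x 4 CRUs,
#' 16 x 4 x 2 mitochondria) is the calibrated desk-scale model on which all
#' shipped analyses run; `"full"` is the full-cell geometry
#' (64 x 28 x 12 CRUs, 64 x 14 x 6 mitochondria); `"small"` (4 x 2 x 2
#' CRUs) is a fast harness for unit tests. All presets share the same
#' kinetic constants — only the lattice differs.
#'
#' Units: time ms, voltage mV, cytosolic/SR/mitochondrial Ca2+ and ROS uM,
#' ATP/ADP mM, current densities uA/cm^2, fluxes uM/ms (in the volume of the
#' compartment named first).
#'
#' @param preset one of `"reduced"`, `"full"`, `"small"`.
#' @return nested named list with elements `geometry`, `membrane`,
#'   `stimulus`, `ryr`, `lcc`, `serca`, `cru`, `mito`, `mptp`, `signaling`,
#'   `engine`, `analysis`.
#' @export
default_params <- function(preset = c("reduced", "full", "small")) {
  preset <- match.arg(preset)
  geom <- switch(preset,
    reduced = list(cru_dims = c(16L, 8L, 4L), mito_dims = c(16L, 4L, 2L)),
    full    = list(cru_dims = c(64L, 28L, 12L), mito_dims = c(64L, 14L, 6L)),
    small   = list(cru_dims = c(4L, 2L, 2L), mito_dims = c(4L, 1L, 1L)))

  list(
    preset = preset,
    geometry = geom,

    membrane = list(
      Cm = 1,                # uF/cm^2
      v_rest = -84,          # initial V (mV)
      e_na = 65, e_k = -87, e_ca = 60,
      g_na = 12, g_nal = 0.004,
      g_k1 = 0.47,
      g_kr = 0.03, tau_xr = 80,
      g_ks = 0.03, tau_xs = 400,
      g_tof = 0.05, tau_xtof = 3.5, tau_ytof = 20,
      g_tos = 0.04, tau_ytos = 200,
      g_nak = 1.3,
      g_katp = 0.05, katp_km = 0.25,   # I_KATP half-activation ATP (mM)
      g_cab = 0.0008,
      c_ncx = 50                       # uA/cm^2 per uM/ms whole-cell NCX flux
    ),

    stimulus = list(amplitude = -80, duration = 0.5, period = 500),

    ryr = list(
      n_ryr = 100L,            # channels per cluster
      k_base_ku = 5e-5,        # composite closed->open rate constant (1/(uM^2 ms))
      k21 = 0.06,              # open -> refractory (closing) rate (1/ms)
      k_rec = 3e-2,            # refractory -> closed recovery rate (1/ms, JSR-saturated)
      km_rec = 500,            # uM JSR half-max of store-dependent recovery
      h_rec = 2,               # Hill steepness of the store-dependence
      dk_camk_max = 2, km_cam_ryr = 0.3, h_cam_ryr = 2,
      dk_ros_max = 5, km_ros_ryr = 1.6, h_ros_ryr = 4
    ),

    lcc = list(
      n_lcc = 5L,              # channels per CRU
      k_open_max = 0.15,       # 1/ms at depolarized V
      v_half = -2, v_slope = 6.5,
      k_close = 1.2,           # 1/ms baseline closing
      k_cdi = 300,             # uM dyadic Ca for Ca-dependent inactivation
      tau_y = 188, y_vhalf = -28, y_slope = 5.5,  # voltage-dependent inactivation
      j_flux = 0.1,            # uM*vol/ms influx per open channel at max driving
      g_cur = 1.15,            # uA/cm^2 per open-channel fraction (current scale)
      camk_avail = 0.3         # fractional availability gain per unit CaMKII act
    ),

    serca = list(
      v_up = 0.8,              # uM/ms maximal uptake (cytosolic volume)
      k_i = 0.62,              # uM half-max
      kd_ros = 1.2, h_ros_serca = 2,
      km_up_atp = 0.01, ki_up = 0.14, ki_up_prime = 5.1,   # mM
      plb_max = 0.32, plb_km = 0.06, plb_h = 2
    ),

    cru = list(
      # relative compartment volumes (cytosol of one CRU = 1)
      v_p = 5e-4, v_s = 0.1, v_i = 1, v_nsr = 0.02, v_jsr = 0.018,
      # instantaneous-buffer scaling factors (fraction of flux appearing as
      # free Ca2+)
      beta_p = 1, beta_s = 0.25, beta_i = 0.1, beta_jsr = 0.3,
      g_rel = 7.5e-3,          # uM*vol/ms per unit (cjsr - cp), fully open cluster
      g_pd = 2.0e-3,           # dyad -> submembrane transfer (vol/ms)
      g_sd = 0.7,              # submembrane -> cytosol transfer (vol/ms)
      g_tr = 1.5e-4,           # NSR -> JSR refill (vol/ms)
      g_leak = 1.0e-5,         # NSR -> cytosol background leak (vol/ms)
      d_ci = 0.15,             # inter-CRU cytosolic coupling (vol/ms)
      d_cs = 0.5,              # inter-CRU submembrane coupling (1/ms): spark recruitment
      d_nsr = 0.08,            # inter-CRU NSR coupling (vol/ms)
      v_ncx = 0.28, km_ncx = 1.1,      # NCX extrusion from submembrane
      ncx_vfac = 0.012,        # mild voltage facilitation of NCX (1/mV)
      j_bg = 0.0025,           # background Ca influx (uM*vol/ms into submembrane)
      sr_init = 900,           # initial NSR/JSR free Ca2+ (uM)
      ca_init = 0.1            # initial cytosolic/dyadic Ca2+ (uM)
    ),

    mito = list(
      v_m = 1.0, beta_m = 0.1, cam_init = 0.2,
      v_mcu = 1.2e-2,          # uM*vol/ms MCU scale (per mitochondrion, block mean Ca)
      km_mcu = 0.3,            # uM
      alpha_mcu = 1,
      v_mncx = 1.5e-3, km_mncx = 0.5,
      mncx_scale = 1,
      g_ptp = 5e-4,            # conductive Ca efflux when mPTP open (vol/ms)
      psi_pol = 180,           # polarized |dpsi| (mV)
      tau_psi_dep = 150,       # ms, depolarization relaxation when open
      tau_psi_rep = 600,       # ms, repolarization recovery when closed
      psi_atp_frac = 0.55,     # producing ATP while dpsi > frac * psi_pol
      em_base = 2.5e-5,        # uM/ms ROS emission, polarized (per CRU share)
      em_hi = 1.4e-3           # uM/ms ROS emission, fully depolarized
    ),

    mptp = list(
      alpha0 = 1.0e-5,         # 1/ms base C0->C1 rate
      h_mptp = 2, ca0 = 1.0,   # uM half-max of Ca2+ activation
      kc1o0 = 2.0e-4,          # 1/ms base C1->O rate
      koc1 = 1.0e-3,           # 1/ms O->C1
      kc1c0 = 4.0e-3,          # 1/ms C1->C0
      alpha_mptp = 1
    ),

    signaling = list(
      ros_base = 0.1,          # uM baseline cytosolic ROS
      k_scav = 2.5e-4,         # 1/ms first-order ROS scavenging
      d_ros = 1e-3,            # inter-CRU ROS coupling (1/ms)
      camkii_rest = 0.004,     # resting activation fraction (0.4%)
      camkii_amax = 0.98,
      camkii_w_ca = 0.12, camkii_km_ca = 0.45,
      camkii_w_ros = 1.0, camkii_km_ros = 1.0,
      camkii_k0 = 2.0101e-7, camkii_kauto = 2.88487e-5,
      camkii_koff = 5.59559e-6,          # calibrated to the activation anchors
      atp_rest = 8, atp_pool = 8.1, atp_max = 8, atp_min = 0.5,
      atp_drop = 9.5,          # mM scale of the production deficit
      atp_pow = 0.5,           # sublinear shape of the deficit dependence
      tau_atp = 2.5e5          # ms (250 s)
    ),

    engine = list(
      dt_normal = 0.01, dt_upstroke = 0.001,
      upstroke_dvdt = 5,       # mV/ms threshold engaging dt_upstroke
      output_interval = 1      # ms
    ),

    analysis = list(alternans_threshold = 0.01)  # uM
  )
}

#' Read a model configuration from a structured text (YAML) file
#'
#' The file may specify any subset of the parameter tree returned by
#' [default_params()]; unspecified entries keep their preset defaults. A
#' top-level `preset` key selects the base preset.
#'
#' @param path YAML file path.
#' @return full parameter list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset %||% "reduced"
  params <- default_params(preset)
  modify_params(params, cfg[setdiff(names(cfg), "preset")])
}

#' Write a model configuration to a structured text (YAML) file
#'
#' @param params parameter list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}

#' Override entries of a parameter list
#'
#' Recursively merges `overrides` into `params`, so
#' `modify_params(default_params(), list(mptp = list(alpha_mptp = 60)))`
#' changes one constant and keeps everything else.
#'
#' @param params parameter list.
#' @param overrides nested list of replacements.
#' @return merged parameter list.
#' @export
modify_params <- function(params, overrides) {
  if (is.null(overrides)) return(params)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(params[[nm]]))
      params[[nm]] <- modify_params(params[[nm]], overrides[[nm]])
    else
      params[[nm]] <- overrides[[nm]]
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a
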