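// Lattice simulation core: coupled CRU and mitochondrion networks with
// stochastic RyR / LCC / mPTP gating, explicit Euler for the continuous
// variables, and global adaptive time stepping during the AP upstroke.
//
// Everything here is driven by the parameter list assembled in R
// (default_params()); no constants are hidden in this file except pure
// numerics (probability caps, sampling cutoffs).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Per-site RNG: xoshiro256++ streams seeded from the master seed through
// splitmix64, one independent stream per lattice site, so sampled
// trajectories do not depend on iteration order.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master + 0x9E3779B97F4A7C15ULL * (stream + 1);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Exact inversion sampling of Binomial(n, p). Fast path: when n*p is tiny
// the probability of more than one event is O((np)^2) and a single uniform
// decides 0 vs 1 events.
static inline int rbinom_site(Xoshiro &rng, int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  double np = n * (double)p;
  if (np < 1e-4) return (rng.unif() < np) ? 1 : 0;
  double q = 1.0 - p, s = p / q;
  double f = std::exp(n * std::log(q));
  double u = rng.unif();
  int k = 0;
  while (u > f && k < n) {
    u -= f;
    ++k;
    f *= s * (n - k + 1.0) / k;
  }
  return k;
}

// Inversion with precomputed P(X = 0) = q^n (used where p is shared across
// sites and q^n can be tabulated once per step).
static inline int rbinom_f0(Xoshiro &rng, int n, double p, double f0) {
  if (n <= 0 || p <= 0.0) return 0;
  double np = n * (double)p;
  if (np < 1e-4) return (rng.unif() < np) ? 1 : 0;
  double s = p / (1.0 - p);
  double f = f0, u = rng.unif();
  int k = 0;
  while (u > f && k < n) {
    u -= f;
    ++k;
    f *= s * (n - k + 1.0) / k;
  }
  return k;
}

static inline double getd(const List &l, const char *nm) {
  return as<double>(l[nm]);
}
static inline int geti(const List &l, const char *nm) {
  return as<int>(l[nm]);
}

// LR-type fast Na+ gate rates
static inline void na_rates(double V, double &am, double &bm, double &ah,
                            double &bh, double &aj, double &bj) {
  double dv = V + 47.13;
  am = (std::fabs(dv) < 1e-6) ? 3.2 : 0.32 * dv / (1.0 - std::exp(-0.1 * dv));
  bm = 0.08 * std::exp(-V / 11.0);
  if (V < -40.0) {
    ah = 0.135 * std::exp(-(80.0 + V) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
}

static inline double rush_larsen(double g, double ginf, double tau, double dt) {
  return ginf + (g - ginf) * std::exp(-dt / tau);
}

// clamp target codes (keep in step with R clamp_code())
enum ClampTarget { CL_ROS = 1, CL_CAMKII = 2, CL_ATP = 3, CL_CAMITO = 4,
                   CL_CACYT = 5, CL_MPTP_CLOSED = 6 };

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List params, List geom, List protocol, double seed,
                 Nullable<List> init_state, bool return_trace = true) {
  // ---- unpack geometry -----------------------------------------------------
  const int ncru = geti(geom, "cru_count");
  const int nmito = geti(geom, "mito_count");
  IntegerMatrix nbr = geom["nbr"];          // ncru x 6, 0-based, -1 padded
  IntegerVector mito_of = geom["mito_of"];  // 0-based, length ncru
  const int block_n = ncru / nmito;

  // ---- unpack parameters ---------------------------------------------------
  List mem = params["membrane"], stim = params["stimulus"], ryr = params["ryr"],
       lcc = params["lcc"], ser = params["serca"], cru = params["cru"],
       mit = params["mito"], mpt = params["mptp"], sgn = params["signaling"],
       eng = params["engine"];

  const double Cm = getd(mem, "Cm"), e_na = getd(mem, "e_na"),
               e_k = getd(mem, "e_k"), e_ca = getd(mem, "e_ca");
  const double g_na = getd(mem, "g_na"), g_nal = getd(mem, "g_nal"),
               g_k1 = getd(mem, "g_k1"), g_kr = getd(mem, "g_kr"),
               tau_xr = getd(mem, "tau_xr"), g_ks = getd(mem, "g_ks"),
               tau_xs = getd(mem, "tau_xs"), g_tof = getd(mem, "g_tof"),
               tau_xtof = getd(mem, "tau_xtof"), tau_ytof = getd(mem, "tau_ytof"),
               g_tos = getd(mem, "g_tos"), tau_ytos = getd(mem, "tau_ytos"),
               g_nak = getd(mem, "g_nak"), g_katp = getd(mem, "g_katp"),
               katp_km = getd(mem, "katp_km"), g_cab = getd(mem, "g_cab"),
               c_ncx = getd(mem, "c_ncx");
  const double stim_amp = getd(stim, "amplitude"),
               stim_dur = getd(stim, "duration");

  const int n_ryr = geti(ryr, "n_ryr");
  const double kbku = getd(ryr, "k_base_ku"), k21 = getd(ryr, "k21"),
               k_rec = getd(ryr, "k_rec"), km_rec = getd(ryr, "km_rec"),
               h_rec = getd(ryr, "h_rec");
  const double dk_camk_max = getd(ryr, "dk_camk_max"),
               km_cam_ryr = getd(ryr, "km_cam_ryr"),
               h_cam_ryr = getd(ryr, "h_cam_ryr");
  double dk_ros_max = getd(ryr, "dk_ros_max");
  const double km_ros_ryr = getd(ryr, "km_ros_ryr"),
               h_ros_ryr = getd(ryr, "h_ros_ryr");

  const int n_lcc = geti(lcc, "n_lcc");
  const double lcc_komax = getd(lcc, "k_open_max"),
               lcc_vh = getd(lcc, "v_half"), lcc_vs = getd(lcc, "v_slope"),
               lcc_kc = getd(lcc, "k_close"), lcc_kcdi = getd(lcc, "k_cdi"),
               lcc_jflux = getd(lcc, "j_flux"), lcc_gcur = getd(lcc, "g_cur"),
               lcc_camk = getd(lcc, "camk_avail"),
               lcc_tauy = getd(lcc, "tau_y"), lcc_yvh = getd(lcc, "y_vhalf"),
               lcc_ys = getd(lcc, "y_slope");

  const double v_up = getd(ser, "v_up"), k_i = getd(ser, "k_i"),
               kd_ros = getd(ser, "kd_ros"), h_ros_serca = getd(ser, "h_ros_serca"),
               km_up_atp = getd(ser, "km_up_atp"), ki_up = getd(ser, "ki_up"),
               ki_up_prime = getd(ser, "ki_up_prime"),
               plb_max = getd(ser, "plb_max"), plb_km = getd(ser, "plb_km"),
               plb_h = getd(ser, "plb_h");

  const double v_p = getd(cru, "v_p"), v_s = getd(cru, "v_s"),
               v_i = getd(cru, "v_i"), v_nsr = getd(cru, "v_nsr"),
               v_jsr = getd(cru, "v_jsr"), beta_p = getd(cru, "beta_p"),
               beta_s = getd(cru, "beta_s"), beta_i = getd(cru, "beta_i"),
               beta_jsr = getd(cru, "beta_jsr"), g_rel = getd(cru, "g_rel"),
               g_pd = getd(cru, "g_pd"), g_sd = getd(cru, "g_sd"),
               g_tr = getd(cru, "g_tr"), g_leak = getd(cru, "g_leak"),
               d_ci = getd(cru, "d_ci"), d_cs = getd(cru, "d_cs"),
               d_nsr = getd(cru, "d_nsr"), v_ncx = getd(cru, "v_ncx"),
               km_ncx = getd(cru, "km_ncx"), ncx_vfac = getd(cru, "ncx_vfac"),
               j_bg = getd(cru, "j_bg"), sr_init = getd(cru, "sr_init"),
               ca_init = getd(cru, "ca_init");

  const double v_m = getd(mit, "v_m"), beta_m = getd(mit, "beta_m"),
               v_mcu = getd(mit, "v_mcu"), km_mcu = getd(mit, "km_mcu"),
               v_mncx = getd(mit, "v_mncx"), km_mncx = getd(mit, "km_mncx"),
               g_ptp = getd(mit, "g_ptp"), psi_pol = getd(mit, "psi_pol"),
               tau_psi_dep = getd(mit, "tau_psi_dep"),
               tau_psi_rep = getd(mit, "tau_psi_rep"),
               psi_atp_frac = getd(mit, "psi_atp_frac"),
               em_base = getd(mit, "em_base"), em_hi = getd(mit, "em_hi"),
               cam_init = getd(mit, "cam_init");

  const double alpha0 = getd(mpt, "alpha0"), h_mptp = getd(mpt, "h_mptp"),
               ca0 = getd(mpt, "ca0"), kc1o0 = getd(mpt, "kc1o0"),
               koc1 = getd(mpt, "koc1"), kc1c0 = getd(mpt, "kc1c0");

  const double ros_base = getd(sgn, "ros_base"), k_scav = getd(sgn, "k_scav"),
               d_ros = getd(sgn, "d_ros"),
               camkii_rest = getd(sgn, "camkii_rest"),
               camkii_amax = getd(sgn, "camkii_amax"),
               ck_wca = getd(sgn, "camkii_w_ca"), ck_kmca = getd(sgn, "camkii_km_ca"),
               ck_wros = getd(sgn, "camkii_w_ros"), ck_kmros = getd(sgn, "camkii_km_ros"),
               ck_k0 = getd(sgn, "camkii_k0"), ck_kauto = getd(sgn, "camkii_kauto"),
               ck_koff = getd(sgn, "camkii_koff"),
               atp_rest = getd(sgn, "atp_rest"), atp_pool = getd(sgn, "atp_pool"),
               atp_max = getd(sgn, "atp_max"), atp_min = getd(sgn, "atp_min"),
               atp_drop = getd(sgn, "atp_drop"), atp_pow = getd(sgn, "atp_pow"),
               tau_atp = getd(sgn, "tau_atp");

  const double dt_normal = getd(eng, "dt_normal"),
               dt_upstroke = getd(eng, "dt_upstroke"),
               upstroke_dvdt = getd(eng, "upstroke_dvdt"),
               out_interval = getd(eng, "output_interval");

  // ---- protocol ------------------------------------------------------------
  const double pcl = getd(protocol, "pcl");
  const double duration = getd(protocol, "duration");
  const bool stim_on = as<bool>(protocol["stim_on"]);
  const double alpha_mptp = getd(protocol, "alpha_mptp");
  const double alpha_mcu = getd(protocol, "alpha_mcu");
  const double mncx_scale = getd(protocol, "mncx_scale");
  const bool ryr_redox_off = as<bool>(protocol["ryr_redox_off"]);
  const bool serca_redox_off = as<bool>(protocol["serca_redox_off"]);
  const bool sarco_open = as<bool>(protocol["sarco_open"]);
  const bool mito_on = as<bool>(protocol["mito_on"]);
  IntegerVector cl_target = protocol["clamp_target"];
  NumericVector cl_value = protocol["clamp_value"];
  NumericVector cl_start = protocol["clamp_start"];
  const int n_clamp = cl_target.size();
  if (ryr_redox_off) dk_ros_max = 0.0;

  const double kc1o = alpha_mptp * kc1o0;

  // ---- state ---------------------------------------------------------------
  std::vector<double> cp(ncru), cs(ncru), ci(ncru), cnsr(ncru), cjsr(ncru),
      ros(ncru), ci_new(ncru), cs_new(ncru), cnsr_new(ncru), ros_new(ncru);
  std::vector<int> nro(ncru), nrf(ncru), nlo(ncru);
  std::vector<double> cam(nmito), dpsi(nmito);
  std::vector<int> mst(nmito);
  std::vector<Xoshiro> rng(ncru + nmito);
  double V, gm, gh, gj, gxr, gxs, gxtof, gytof, gytos, gylcc;
  double camkii, atp;
  double t = 0.0, dvdt_prev = 0.0;

  uint64_t master = (uint64_t)(int64_t)seed;
  for (int i = 0; i < ncru + nmito; ++i) rng[i].seed(master, (uint64_t)i);

  bool resumed = false;
  if (init_state.isNotNull()) {
    List st(init_state);
    resumed = true;
    t = getd(st, "t");
    V = getd(st, "V");
    NumericVector g = st["gates"];
    gm = g[0]; gh = g[1]; gj = g[2]; gxr = g[3]; gxs = g[4];
    gxtof = g[5]; gytof = g[6]; gytos = g[7]; gylcc = g[8];
    NumericVector a;
    a = st["ca_p"];   std::copy(a.begin(), a.end(), cp.begin());
    a = st["ca_s"];   std::copy(a.begin(), a.end(), cs.begin());
    a = st["ca_i"];   std::copy(a.begin(), a.end(), ci.begin());
    a = st["ca_nsr"]; std::copy(a.begin(), a.end(), cnsr.begin());
    a = st["ca_jsr"]; std::copy(a.begin(), a.end(), cjsr.begin());
    a = st["ros"];    std::copy(a.begin(), a.end(), ros.begin());
    a = st["ca_m"];   std::copy(a.begin(), a.end(), cam.begin());
    a = st["dpsi"];   std::copy(a.begin(), a.end(), dpsi.begin());
    IntegerVector iv;
    iv = st["ryr_open"]; std::copy(iv.begin(), iv.end(), nro.begin());
    iv = st["ryr_refr"]; std::copy(iv.begin(), iv.end(), nrf.begin());
    iv = st["lcc_open"]; std::copy(iv.begin(), iv.end(), nlo.begin());
    iv = st["mptp_state"]; std::copy(iv.begin(), iv.end(), mst.begin());
    camkii = getd(st, "camkii_act");
    atp = getd(st, "atp");
    dvdt_prev = getd(st, "dvdt");
    NumericMatrix rs = st["rng_state"];
    for (int i = 0; i < ncru + nmito; ++i)
      for (int w = 0; w < 4; ++w) {
        uint64_t hi = (uint64_t)(uint32_t)rs(i, 2 * w);
        uint64_t lo = (uint64_t)(uint32_t)rs(i, 2 * w + 1);
        rng[i].s[w] = (hi << 32) | lo;
      }
  } else {
    V = getd(mem, "v_rest");
    double am, bm, ah, bh, aj, bj;
    na_rates(V, am, bm, ah, bh, aj, bj);
    gm = am / (am + bm); gh = ah / (ah + bh); gj = aj / (aj + bj);
    gxr = 1.0 / (1.0 + std::exp(-(V + 21.5) / 7.5));
    gxs = 1.0 / (1.0 + std::exp(-(V - 1.5) / 16.7));
    gxtof = 1.0 / (1.0 + std::exp(-(V + 3.0) / 15.0));
    gytof = 1.0 / (1.0 + std::exp((V + 33.5) / 10.0));
    gytos = gytof;
    gylcc = 1.0 / (1.0 + std::exp((V - lcc_yvh) / lcc_ys));
    for (int i = 0; i < ncru; ++i) {
      cp[i] = cs[i] = ci[i] = ca_init;
      cnsr[i] = cjsr[i] = sr_init;
      ros[i] = ros_base;
      nro[i] = 0; nrf[i] = 0; nlo[i] = 0;
    }
    for (int m = 0; m < nmito; ++m) {
      cam[m] = cam_init; dpsi[m] = psi_pol; mst[m] = 0;
    }
    camkii = camkii_rest;
    atp = atp_rest;
  }

  // ---- carried whole-cell accumulators (recomputable from state) -----------
  double sum_ci = 0, sum_cs = 0, sum_jncx = 0, nlo_total = 0;
  std::vector<double> blk_ci(nmito, 0.0);
  {
    std::fill(blk_ci.begin(), blk_ci.end(), 0.0);
    for (int i = 0; i < ncru; ++i) {
      sum_ci += ci[i]; sum_cs += cs[i]; nlo_total += nlo[i];
      sum_jncx += v_ncx * cs[i] / (cs[i] + km_ncx) *
                  (1.0 + ncx_vfac * (V + 80.0));
      blk_ci[mito_of[i]] += ci[i];
    }
  }
  double f_producing = 0.0;
  for (int m = 0; m < nmito; ++m)
    if (dpsi[m] > psi_atp_frac * psi_pol) f_producing += 1.0;
  f_producing /= nmito;

  // ---- output --------------------------------------------------------------
  const int ncol = 17;
  int nrow = return_trace ? (int)(duration / out_interval) + 2 : 1;
  NumericMatrix trace(nrow, ncol);
  int row = 0;
  double next_out = t;       // sample immediately, then every out_interval
  const double t_end = t + duration;

  double sum_jup = 0, sum_jrel = 0, sum_cjsr = 0, sum_cnsr = 0, sum_ros = 0;
  {
    for (int i = 0; i < ncru; ++i) {
      sum_cjsr += cjsr[i]; sum_cnsr += cnsr[i]; sum_ros += ros[i];
    }
  }

  // RyR closing probability tables for the two step sizes: q^k for k open
  std::vector<double> f0_ryr_normal(n_ryr + 1), f0_ryr_up(n_ryr + 1);
  {
    double pn = -std::expm1(-k21 * dt_normal);
    double pu = -std::expm1(-k21 * dt_upstroke);
    f0_ryr_normal[0] = f0_ryr_up[0] = 1.0;
    for (int k = 1; k <= n_ryr; ++k) {
      f0_ryr_normal[k] = f0_ryr_normal[k - 1] * (1.0 - pn);
      f0_ryr_up[k] = f0_ryr_up[k - 1] * (1.0 - pu);
    }
  }
  const double p21_normal = -std::expm1(-k21 * dt_normal);
  const double p21_up = -std::expm1(-k21 * dt_upstroke);


  const double hr2 = h_ros_ryr, hs2 = h_ros_serca;  // fast path when == 2
  const bool hr_is2 = std::fabs(hr2 - 2.0) < 1e-12;
  const bool hs_is2 = std::fabs(hs2 - 2.0) < 1e-12;

  // flat row-major neighbour table and reusable per-step buffers
  std::vector<int> nbr_flat(ncru * 6);
  for (int i = 0; i < ncru; ++i)
    for (int k = 0; k < 6; ++k) nbr_flat[i * 6 + k] = nbr(i, k);
  std::vector<double> mito_dci(nmito), mito_em(nmito), blk_ci_new(nmito);

  long step = 0;
  while (t < t_end - 1e-9) {
    bool upstroke = std::fabs(dvdt_prev) > upstroke_dvdt;
    // the step is never trimmed to land exactly on t_end: resuming from a
    // snapshot must reproduce the uninterrupted step sequence bit for bit
    double dt = upstroke ? dt_upstroke : dt_normal;

    // ---- stimulus ----------------------------------------------------------
    double i_sti = 0.0;
    if (stim_on && sarco_open) {
      double phase = t - std::floor(t / pcl) * pcl;
      if (phase < stim_dur) i_sti = stim_amp;
    }

    // ---- whole-cell means from carried sums --------------------------------
    double ci_mean = sum_ci / ncru;
    double cs_mean = sum_cs / ncru;
    double ros_mean = sum_ros / ncru;
    double jncx_mean = sum_jncx / ncru;

    // ---- membrane currents (membrane-equation sign: positive depolarizes) --
    double i_na_c = g_na * gm * gm * gm * gh * gj * (V - e_na);
    double mlinf = 1.0 / (1.0 + std::exp(-(V + 47.1) / 3.0));
    double i_nal_c = g_nal * mlinf * (V - e_na);
    double drive_ca = V - e_ca;
    double i_cal_c = sarco_open
        ? lcc_gcur * (nlo_total / (double)ncru) * drive_ca : 0.0;
    double i_ncx_c = sarco_open ? -c_ncx * jncx_mean * beta_i : 0.0;
    double ak1 = 1.02 / (1.0 + std::exp(0.2385 * (V - e_k - 59.215)));
    double bk1 = (0.49124 * std::exp(0.08032 * (V - e_k + 5.476)) +
                  std::exp(0.06175 * (V - e_k - 594.31))) /
                 (1.0 + std::exp(-0.5143 * (V - e_k + 4.753)));
    double i_k1_c = g_k1 * ak1 / (ak1 + bk1) * (V - e_k);
    double rkr = 1.0 / (1.0 + std::exp((V + 9.0) / 22.4));
    double i_kr_c = g_kr * gxr * rkr * (V - e_k);
    double i_ks_c = g_ks * gxs * gxs * (V - e_k);
    double i_tof_c = g_tof * gxtof * gytof * (V - e_k);
    double i_tos_c = g_tos * gxtof * gytos * (V - e_k);
    double fnak = 1.0 / (1.0 + std::exp(-(V + 60.0) / 40.0));
    double i_nak_c = g_nak * fnak;
    double ratp = atp / katp_km;
    double i_katp_c = g_katp / (1.0 + ratp * ratp) * (V - e_k);
    double i_cab_c = g_cab * (V - e_ca);
    // conventional currents above are outward-positive; the membrane
    // equation sums them with a depolarizing-positive sign, so flip.
    double sumI = -(i_na_c + i_nal_c + i_cal_c + i_k1_c + i_kr_c + i_ks_c +
                    i_tof_c + i_tos_c + i_nak_c + i_katp_c + i_cab_c) +
                  (-i_ncx_c);
    double dvdt = (sumI - i_sti) / Cm;
    double V_new = V + dt * dvdt;

    // ---- gate updates (Rush-Larsen) ----------------------------------------
    {
      double am, bm, ah, bh, aj, bj;
      na_rates(V, am, bm, ah, bh, aj, bj);
      double sm = am + bm, sh = ah + bh, sj = aj + bj;
      gm = rush_larsen(gm, am / sm, 1.0 / sm, dt);
      gh = rush_larsen(gh, ah / sh, 1.0 / sh, dt);
      gj = rush_larsen(gj, aj / sj, 1.0 / sj, dt);
      gxr = rush_larsen(gxr, 1.0 / (1.0 + std::exp(-(V + 21.5) / 7.5)), tau_xr, dt);
      gxs = rush_larsen(gxs, 1.0 / (1.0 + std::exp(-(V - 1.5) / 16.7)), tau_xs, dt);
      gxtof = rush_larsen(gxtof, 1.0 / (1.0 + std::exp(-(V + 3.0) / 15.0)), tau_xtof, dt);
      double yinf = 1.0 / (1.0 + std::exp((V + 33.5) / 10.0));
      gytof = rush_larsen(gytof, yinf, tau_ytof, dt);
      gytos = rush_larsen(gytos, yinf, tau_ytos, dt);
      double ylinf = 1.0 / (1.0 + std::exp((V - lcc_yvh) / lcc_ys));
      gylcc = rush_larsen(gylcc, ylinf, lcc_tauy, dt);
    }

    // ---- global modulation factors -----------------------------------------
    // CaMKII-dependent RyR increment (activation is whole-cell)
    double dk_camk = 0.0;
    if (camkii > 0.0)
      dk_camk = dk_camk_max /
                (1.0 + std::pow(km_cam_ryr / camkii, h_cam_ryr));
    // SERCA ATP factor and effective half-max (phospholamban shift)
    double adp = atp_pool - atp;
    double f_atp = 1.0 / (1.0 + adp / ki_up_prime +
                          (1.0 + adp / ki_up) * km_up_atp / atp);
    double plb = plb_max * std::pow(camkii, plb_h) /
                 (std::pow(camkii, plb_h) + std::pow(plb_km, plb_h));
    double khalf = k_i - plb;
    if (khalf <= 0.0) stop("effective SERCA half-max <= 0 (k_i - PLB)");
    double khalf2 = khalf * khalf;
    double vup_eff = v_up * f_atp;
    // LCC opening rate (voltage part shared by all CRUs)
    double finf = 1.0 / (1.0 + std::exp(-(V - lcc_vh) / lcc_vs));
    double avail = (1.0 + lcc_camk * camkii) * gylcc;
    double k_open = lcc_komax * finf * avail;
    double p_open = (k_open * dt < 1e-3) ? k_open * dt : -std::expm1(-k_open * dt);
    if (k_open * dt > 2.0)
      stop("LCC opening rate unresolved (k*dt > 2) at t=%.3f ms; reduce dt", t);
    // table of (1-p_open)^k, k = 0..n_lcc
    double f0_lcc[64];
    f0_lcc[0] = 1.0;
    for (int k = 1; k <= n_lcc; ++k) f0_lcc[k] = f0_lcc[k - 1] * (1.0 - p_open);
    const double p21 = upstroke ? p21_up : p21_normal;
    const std::vector<double> &f0_ryr = upstroke ? f0_ryr_up : f0_ryr_normal;

    // ---- mitochondrion loop ------------------------------------------------
    // uses block-mean cytosolic Ca from the carried sums (previous update)
    double open_cnt = 0.0, dpsi_sum = 0.0, cam_sum = 0.0, prod_cnt = 0.0;
    for (int m = 0; m < nmito; ++m) {
      double cib = blk_ci[m] / block_n;
      double F_mcu = 0.0, F_mncx = 0.0, F_ptp = 0.0;
      if (mito_on) {
        double c2 = cib * cib;
        F_mcu = alpha_mcu * v_mcu * (dpsi[m] / psi_pol) * c2 / (c2 + km_mcu * km_mcu);
        F_mncx = mncx_scale * v_mncx * cam[m] / (cam[m] + km_mncx);
        if (mst[m] == 2) F_ptp = g_ptp * (cam[m] - cib);
      }
      double cam_new = cam[m] + dt * (beta_m / v_m) * (F_mcu - F_mncx - F_ptp);
      if (cam_new < 0.0) cam_new = 0.0;

      // mPTP 3-state transitions (single channel per mitochondrion)
      int st = mst[m];
      Xoshiro &r = rng[ncru + m];
      double ch = std::pow(cam[m], h_mptp);
      double kc0c1 = alpha0 * (1.0 + 199.0 * ch / (ch + std::pow(ca0, h_mptp)));
      if (st == 0) {
        if (r.unif() < kc0c1 * dt) st = 1;
      } else if (st == 1) {
        double u = r.unif();
        double p1 = kc1o * dt;
        if (u < p1) st = 2;
        else if (u < p1 + kc1c0 * dt) st = 0;
      } else {
        if (r.unif() < koc1 * dt) st = 1;
      }
      mst[m] = st;
      cam[m] = cam_new;

      // membrane potential relaxation and ROS emission
      double target = (st == 2) ? 0.0 : psi_pol;
      double tau = (st == 2) ? tau_psi_dep : tau_psi_rep;
      dpsi[m] += dt * (target - dpsi[m]) / tau;
      double em = em_hi - (em_hi - em_base) * (dpsi[m] / psi_pol);
      mito_em[m] = em;
      mito_dci[m] = (F_mncx + F_ptp - F_mcu) / block_n;  // per CRU of block

      if (st == 2) open_cnt += 1.0;
      dpsi_sum += dpsi[m];
      cam_sum += cam[m];
      if (dpsi[m] > psi_atp_frac * psi_pol) prod_cnt += 1.0;
    }
    f_producing = prod_cnt / nmito;

    // ---- CRU loop ----------------------------------------------------------
    double nsum_ci = 0, nsum_cs = 0, nsum_jncx = 0, nsum_ros = 0;
    double nsum_cjsr = 0, nsum_cnsr = 0, njup = 0, njrel = 0;
    double nlo_tot_new = 0;
    std::fill(blk_ci_new.begin(), blk_ci_new.end(), 0.0);
    double drive_flux = (drive_ca < 0.0) ? -drive_ca / (e_ca + 80.0) : 0.0;

    for (int i = 0; i < ncru; ++i) {
      Xoshiro &r = rng[i];
      int m = mito_of[i];

      // --- stochastic LCC gating (open channels close with Ca-dependent
      //     inactivation sensed in the dyad) ---
      int open_l = nlo[i];
      int closed_l = n_lcc - open_l;
      int n_o = 0, n_c = 0;
      if (closed_l > 0 && p_open > 0.0 && sarco_open)
        n_o = rbinom_f0(r, closed_l, p_open, f0_lcc[closed_l]);
      if (open_l > 0) {
        double kcl = lcc_kc * (1.0 + cp[i] / lcc_kcdi);
        double pcl_ = kcl * dt;
        if (pcl_ > 2.0)
          stop("LCC closing rate unresolved (k*dt > 2) at t=%.3f ms; reduce dt", t);
        if (pcl_ * open_l >= 1e-4) pcl_ = -std::expm1(-kcl * dt);
        n_c = rbinom_site(r, open_l, pcl_);
      }
      open_l += n_o - n_c;
      nlo[i] = open_l;
      nlo_tot_new += open_l;

      // --- stochastic RyR gating: k12 from dyadic Ca with CaMKII and ROS
      //     increments ---
      double dk_ros_i = 0.0;
      if (dk_ros_max > 0.0 && ros[i] > 0.0) {
        double y = hr_is2 ? (ros[i] / km_ros_ryr) * (ros[i] / km_ros_ryr)
                          : std::pow(ros[i] / km_ros_ryr, hr2);
        dk_ros_i = dk_ros_max * y / (1.0 + y);
      }
      double k12 = kbku * (1.0 + dk_camk + dk_ros_i) * cp[i] * cp[i];
      if (k12 * dt > 2.0)
        stop("RyR opening rate unresolved (k12*dt > 2) at t=%.3f ms; reduce dt", t);
      int open_r = nro[i];
      int refr_r = nrf[i];
      int closed_r = n_ryr - open_r - refr_r;
      double p12 = (k12 * dt < 1e-3) ? k12 * dt : -std::expm1(-k12 * dt);
      int r_o = (closed_r > 0) ? rbinom_site(r, closed_r, p12) : 0;
      int r_c = (open_r > 0) ? rbinom_f0(r, open_r, p21, f0_ryr[open_r]) : 0;
      // store-dependent restitution: recovery gated steeply by JSR refill
      double xr_ = cjsr[i] / km_rec, xh;
      if (h_rec == 6.0) { double x2 = xr_ * xr_; xh = x2 * x2 * x2; }
      else if (h_rec == 4.0) { double x2 = xr_ * xr_; xh = x2 * x2; }
      else if (h_rec == 2.0) { xh = xr_ * xr_; }
      else if (h_rec == 1.0) { xh = xr_; }
      else xh = std::pow(xr_, h_rec);
      double krec_eff = k_rec * xh / (1.0 + xh);
      int r_rec = (refr_r > 0) ? rbinom_site(r, refr_r, krec_eff * dt) : 0;
      open_r += r_o - r_c;
      refr_r += r_c - r_rec;
      nro[i] = open_r;
      nrf[i] = refr_r;

      // --- fluxes (uM * volume / ms) ---
      double F_rel = (open_r / (double)n_ryr) * g_rel * (cjsr[i] - cp[i]);
      double F_lcc = sarco_open ? open_l * lcc_jflux * drive_flux : 0.0;
      double F_pd = g_pd * (cp[i] - cs[i]);
      double F_sd = g_sd * (cs[i] - ci[i]);
      double jncx_i = v_ncx * cs[i] / (cs[i] + km_ncx) *
                      (1.0 + ncx_vfac * (V + 80.0));
      double F_ncx = sarco_open ? v_s * jncx_i : 0.0;
      double F_bg = sarco_open ? j_bg : 0.0;
      // SERCA with local redox factor
      double f_ros_i = 1.0;
      if (!serca_redox_off && ros[i] > 0.0) {
        double x = hs_is2 ? (ros[i] / kd_ros) * (ros[i] / kd_ros)
                          : std::pow(ros[i] / kd_ros, hs2);
        f_ros_i = (1.0 + 0.75 * x) / (1.0 + x);
      }
      double ci2 = ci[i] * ci[i];
      double jup_i = vup_eff * f_ros_i * ci2 / (ci2 + khalf2);
      double F_up = v_i * jup_i;
      double F_tr = g_tr * (cnsr[i] - cjsr[i]);
      double F_leak = g_leak * (cnsr[i] - ci[i]);

      // --- neighbour diffusion (cytosol and NSR) ---
      double lap_ci = 0.0, lap_cs = 0.0, lap_nsr = 0.0, lap_ros = 0.0;
      const int *nb = &nbr_flat[i * 6];
      for (int k = 0; k < 6; ++k) {
        int j = nb[k];
        if (j < 0) break;
        lap_ci += ci[j] - ci[i];
        lap_cs += cs[j] - cs[i];
        lap_nsr += cnsr[j] - cnsr[i];
        lap_ros += ros[j] - ros[i];
      }

      // --- compartment updates ---
      double cp_n = cp[i] + dt * (beta_p / v_p) * (F_lcc + F_rel - F_pd);
      double cs_n = cs[i] + dt * ((beta_s / v_s) * (F_pd - F_sd - F_ncx + F_bg) +
                                  beta_s * d_cs * lap_cs);
      double ci_n = ci[i] + dt * ((beta_i / v_i) *
                    (F_sd - F_up + F_leak + v_i * mito_dci[m] +
                     v_i * d_ci * lap_ci));
      double cnsr_n = cnsr[i] + dt * ((F_up - F_tr - F_leak) / v_nsr +
                                      d_nsr * lap_nsr);
      double cjsr_n = cjsr[i] + dt * (beta_jsr / v_jsr) * (F_tr - F_rel);
      double ros_n = ros[i] + dt * (mito_em[m] - k_scav * ros[i] + d_ros * lap_ros);
      if (cp_n < 0.0) cp_n = 0.0;
      if (cs_n < 0.0) cs_n = 0.0;
      if (ci_n < 0.0) ci_n = 0.0;
      if (cjsr_n < 0.0) cjsr_n = 0.0;
      if (ros_n < 0.0) ros_n = 0.0;

      cp[i] = cp_n; cs_new[i] = cs_n;
      ci_new[i] = ci_n; cnsr_new[i] = cnsr_n; cjsr[i] = cjsr_n;
      ros_new[i] = ros_n;

      nsum_ci += ci_n; nsum_cs += cs_n;
      nsum_ros += ros_n; nsum_cjsr += cjsr_n; nsum_cnsr += cnsr_n;
      njup += jup_i; njrel += F_rel / v_i;
      blk_ci_new[m] += ci_n;
    }
    ci.swap(ci_new);
    cs.swap(cs_new);
    cnsr.swap(cnsr_new);
    ros.swap(ros_new);
    blk_ci.swap(blk_ci_new);

    // NCX accumulator for the next step's current, from the updated state
    // (so it is exactly reconstructible when resuming from a snapshot)
    for (int i = 0; i < ncru; ++i)
      nsum_jncx += v_ncx * cs[i] / (cs[i] + km_ncx) *
                   (1.0 + ncx_vfac * (V_new + 80.0));

    // ---- slow whole-cell variables -----------------------------------------
    {
      double ca2 = ci_mean * ci_mean;
      double ros2 = ros_mean * ros_mean;
      double u = ck_wca * ca2 / (ca2 + ck_kmca * ck_kmca) +
                 ck_wros * ros2 / (ros2 + ck_kmros * ck_kmros);
      camkii += dt * (u * (ck_k0 + ck_kauto * camkii) *
                      (1.0 - camkii / camkii_amax) - ck_koff * camkii);
      if (camkii < 0.0) camkii = 0.0;
      if (camkii > camkii_amax) camkii = camkii_amax;
      double target = atp_max -
                      atp_drop * std::pow(1.0 - f_producing, atp_pow);
      if (target < atp_min) target = atp_min;
      atp += dt * (target - atp) / tau_atp;
      if (atp < atp_min) atp = atp_min;
      if (atp > atp_pool) atp = atp_pool;
    }

    V = V_new;
    dvdt_prev = dvdt;
    t += dt;

    // ---- clamps (overwrite targets after the step) -------------------------
    for (int c = 0; c < n_clamp; ++c) {
      if (t < cl_start[c]) continue;
      double val = cl_value[c];
      switch (cl_target[c]) {
      case CL_ROS:
        std::fill(ros.begin(), ros.end(), val);
        nsum_ros = val * ncru;
        break;
      case CL_CAMKII: camkii = val; break;
      case CL_ATP: atp = val; break;
      case CL_CAMITO:
        std::fill(cam.begin(), cam.end(), val);
        cam_sum = val * nmito;
        break;
      case CL_CACYT: {
        std::fill(ci.begin(), ci.end(), val);
        nsum_ci = val * ncru;
        std::fill(blk_ci.begin(), blk_ci.end(), val * block_n);
        break;
      }
      case CL_MPTP_CLOSED:
        std::fill(mst.begin(), mst.end(), 0);
        open_cnt = 0.0;
        break;
      }
    }

    sum_ci = nsum_ci; sum_cs = nsum_cs; sum_jncx = nsum_jncx;
    sum_ros = nsum_ros; sum_cjsr = nsum_cjsr; sum_cnsr = nsum_cnsr;
    nlo_total = nlo_tot_new;

    // ---- stability check ---------------------------------------------------
    if ((step & 1023) == 0) {
      if (!std::isfinite(V))
        stop("numerical instability: membrane potential V is not finite at t=%.3f ms", t);
      if (!std::isfinite(sum_ci))
        stop("numerical instability: cytosolic Ca2+ is not finite at t=%.3f ms", t);
    }
    ++step;

    // ---- output ------------------------------------------------------------
    if (return_trace && t >= next_out - 1e-9 && row < nrow) {
      trace(row, 0) = t;
      trace(row, 1) = V;
      trace(row, 2) = sum_ci / ncru;
      trace(row, 3) = sum_cs / ncru;
      trace(row, 4) = sum_cjsr / ncru;
      trace(row, 5) = sum_cnsr / ncru;
      trace(row, 6) = cam_sum / nmito;
      trace(row, 7) = open_cnt / nmito;
      trace(row, 8) = dpsi_sum / nmito;
      trace(row, 9) = sum_ros / ncru;
      trace(row, 10) = camkii;
      trace(row, 11) = atp;
      trace(row, 12) = njup / ncru;
      trace(row, 13) = njrel / ncru;
      trace(row, 14) = upstroke ? 1.0 : 0.0;
      trace(row, 15) = f_producing;
      trace(row, 16) = i_sti;
      ++row;
      next_out += out_interval;
    }
    if ((step & 65535) == 0) Rcpp::checkUserInterrupt();
  }

  // ---- snapshot ------------------------------------------------------------
  NumericMatrix rs(ncru + nmito, 8);
  for (int i = 0; i < ncru + nmito; ++i)
    for (int w = 0; w < 4; ++w) {
      rs(i, 2 * w) = (double)(uint32_t)(rng[i].s[w] >> 32);
      rs(i, 2 * w + 1) = (double)(uint32_t)(rng[i].s[w] & 0xFFFFFFFFULL);
    }
  List snap = List::create(
      _["t"] = t, _["V"] = V,
      _["gates"] = NumericVector::create(gm, gh, gj, gxr, gxs, gxtof, gytof,
                                         gytos, gylcc),
      _["ca_p"] = NumericVector(cp.begin(), cp.end()),
      _["ca_s"] = NumericVector(cs.begin(), cs.end()),
      _["ca_i"] = NumericVector(ci.begin(), ci.end()),
      _["ca_nsr"] = NumericVector(cnsr.begin(), cnsr.end()),
      _["ca_jsr"] = NumericVector(cjsr.begin(), cjsr.end()),
      _["ros"] = NumericVector(ros.begin(), ros.end()),
      _["ryr_open"] = IntegerVector(nro.begin(), nro.end()),
      _["ryr_refr"] = IntegerVector(nrf.begin(), nrf.end()),
      _["lcc_open"] = IntegerVector(nlo.begin(), nlo.end()),
      _["ca_m"] = NumericVector(cam.begin(), cam.end()),
      _["dpsi"] = NumericVector(dpsi.begin(), dpsi.end()),
      _["mptp_state"] = IntegerVector(mst.begin(), mst.end()),
      _["camkii_act"] = camkii, _["atp"] = atp,
      _["dvdt"] = dvdt_prev,
      _["rng_state"] = rs,
      _["resumed"] = resumed);

  if (return_trace && row < nrow)
    trace = trace(Range(0, std::max(row - 1, 0)), _);
  return List::create(_["trace"] = trace, _["snapshot"] = snap,
                      _["steps"] = (double)step);
}
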