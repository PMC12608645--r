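#include "network.h"
#include <cmath>
#include <stdexcept>
#include <map>

// ---------------------------------------------------------------------------
// Counter-based RNG (splitmix64): per-cell streams independent of iteration
// order; reproducible under (global seed, cell id, counters).
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix4(uint64_t a, uint64_t b, uint64_t c, uint64_t d) {
  uint64_t h = splitmix64(a ^ 0x8000000080003ULL);
  h = splitmix64(h ^ b);
  h = splitmix64(h ^ c);
  h = splitmix64(h ^ d);
  return h;
}

double msx_runif1(uint64_t seed, uint64_t cell_id, uint64_t c1, uint64_t c2) {
  uint64_t h = mix4(seed, cell_id, c1, c2);
  // 53-bit mantissa uniform in (0,1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

double msx_rnorm1(uint64_t seed, uint64_t cell_id, uint64_t c1, uint64_t c2) {
  double u1 = msx_runif1(seed, cell_id, c1, 2 * c2);
  double u2 = msx_runif1(seed, cell_id, c1, 2 * c2 + 1);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ---------------------------------------------------------------------------
// Parameter table
// ---------------------------------------------------------------------------
#define MSX_PARAMS(X)                                                        \
  X(vmax_glut) X(km_glut)                                                    \
  X(vmax_hk) X(km_hk) X(ki_hk_g6p) X(km_atp_use)                             \
  X(k_pgi) X(keq_pgi)                                                        \
  X(vmax_pfk) X(km_pfk) X(pfk_amp_base) X(km_pfk_amp)                        \
  X(ki_pfk_atp) X(ki_pfk_cit) X(ki_pfk_lac)                                  \
  X(k_ald) X(keq_ald)                                                        \
  X(k_tpi) X(keq_tpi)                                                        \
  X(k_gapdh) X(keq_gapdh) X(km_gapdh_pi)                                     \
  X(k_pgk) X(keq_pgk)                                                        \
  X(k_pgm) X(keq_pgm)                                                        \
  X(k_eno) X(keq_eno)                                                        \
  X(vmax_pk) X(km_pk_pep) X(km_pk_adp)                                       \
  X(k_ldh) X(keq_ldh) X(km_ldh_pyr) X(km_ldh_lac)                            \
  X(vmax_gys) X(km_gys_g6p) X(gly_cap) X(atp_per_gys)                        \
  X(vmax_gp) X(km_gp_gly) X(ki_gp_g6p)                                       \
  X(vmax_atpase) X(km_atpase) X(ampk_demand_w) X(km_ampk_demand)             \
  X(k_ak) X(keq_ak)                                                          \
  X(vmax_shuttle) X(km_shuttle_nadhc) X(km_shuttle_nadm)                     \
  X(vmax_pdh) X(km_pdh_pyr) X(km_nadm) X(ki_pdh_pdk) X(ki_pdh_accoa) X(ki_pdk_pyr) \
  X(k_cs) X(ki_cs_nadh) X(k_aco) X(keq_aco)                                  \
  X(vmax_mct) X(km_mct)                                                      \
  X(vmax_etc) X(km_etc_nadh) X(km_etc_o2) X(km_etc_adp)                      \
  X(vmax_etc2) X(km_etc_fadh2)                                               \
  X(k_idh) X(k_kgdh) X(k_scs) X(km_scs_adp) X(k_sdh) X(km_sdh_fad)           \
  X(k_fh) X(keq_fh) X(k_mdh) X(km_mdh_oaa)                                   \
  X(p_o_nadh) X(p_o_fadh2)                                                   \
  X(k_buf_i) X(ph_i_ref) X(buffer_ratio)                                     \
  X(k_pi_relax) X(pi_ref)                                                    \
  X(ph_mid) X(ph_steep)                                                      \
  X(d_gene) X(d_hif) X(d_prot) X(k_translate)                                \
  X(hif_a0) X(hif_alac) X(km_hif_lac) X(hif_ao2) X(km_hif_o2)                \
  X(kh_gene) X(nh_gene)                                                      \
  X(ldh_b0) X(ldh_bh) X(ldh_bm)                                              \
  X(pdh_b0) X(pdh_bh) X(pdh_ampk_w)                                          \
  X(pdk_b0) X(pdk_bh)                                                        \
  X(glut_b0) X(glut_bh) X(glut_bm)                                           \
  X(mct_b0) X(mct_bh)                                                        \
  X(hk_b0) X(hk_bh) X(hk_bm)                                                 \
  X(pfk_b0) X(pfk_bh) X(pfk_bm)                                              \
  X(myc_b0) X(km_myc)                                                        \
  X(ampk_b0) X(ampk_be) X(km_ampk_adp)

enum ParamIdx {
#define X(nm) P_##nm,
  MSX_PARAMS(X)
#undef X
  N_PARAMS
};

const std::vector<std::string>& param_names() {
  static std::vector<std::string> nm = {
#define X(s) #s,
    MSX_PARAMS(X)
#undef X
  };
  return nm;
}

Params params_from_named(const Rcpp::NumericVector& x) {
  const std::vector<std::string>& nm = param_names();
  Params p;
  p.v.assign(nm.size(), NA_REAL);
  Rcpp::CharacterVector xn = x.names();
  if (xn.size() != x.size())
    Rcpp::stop("parameter vector must be fully named");
  std::map<std::string, double> got;
  for (int i = 0; i < x.size(); ++i)
    got[Rcpp::as<std::string>(xn[i])] = x[i];
  for (size_t i = 0; i < nm.size(); ++i) {
    std::map<std::string, double>::iterator it = got.find(nm[i]);
    if (it == got.end())
      Rcpp::stop("missing metabolic parameter: " + nm[i]);
    p.v[i] = it->second;
    got.erase(it);
  }
  if (!got.empty())
    Rcpp::stop("unknown metabolic parameter: " + got.begin()->first);
  return p;
}

const std::vector<std::string>& state_names() {
  static std::vector<std::string> nm = {
    "glucose_i", "g6p", "f6p", "f16bp", "dhap", "gap", "bpg13", "pg3", "pg2",
    "pep", "pyruvate", "lactate_i", "proton_i", "glycogen",
    "accoa", "citrate", "isocitrate", "akg", "succinyl_coa", "succinate",
    "fumarate", "malate", "oaa",
    "atp", "adp", "amp", "pi",
    "nad_c", "nadh_c", "nad_m", "nadh_m", "fad", "fadh2",
    "HIF1A", "LDH", "PDH", "PDK", "GLUT", "MCT", "HK", "PFK", "MYC", "AMPK",
    "p_HIF1A", "p_LDH", "p_PDH", "p_PDK", "p_GLUT", "p_MCT", "p_HK", "p_PFK",
    "p_MYC", "p_AMPK"
  };
  return nm;
}

// ---------------------------------------------------------------------------
// Kinetics helpers
// ---------------------------------------------------------------------------
static inline double mm(double x, double k) {
  return (x > 0.0) ? x / (k + x) : 0.0;
}
static inline double powi(double t, double n) {
  if (n == 2.0) return t * t;
  if (n == 3.0) return t * t * t;
  if (n == 4.0) { double q = t * t; return q * q; }
  if (n == 1.0) return t;
  return std::pow(t, n);
}
static inline double hill(double x, double k, double n) {
  if (x <= 0.0) return 0.0;
  double r = powi(x / k, n);
  return r / (1.0 + r);
}
static inline double rep(double x, double k, double n) {
  if (x <= 0.0) return 1.0;
  return 1.0 / (1.0 + powi(x / k, n));
}
static inline double ph_of(double h_mM) {
  // h in mM of free protons
  return (h_mM > 0.0) ? -std::log10(h_mM * 1e-3) : 14.0;
}

double ph_factor(double ph, const Params& p) {
  double k = p.get(P_ph_steep), m = p.get(P_ph_mid);
  double s = 1.0 / (1.0 + std::exp(-k * (ph - m)));
  double s0 = 1.0 / (1.0 + std::exp(-k * (7.4 - m)));
  double f = s / s0;
  return (f > 1.0) ? 1.0 : f;
}

// ---------------------------------------------------------------------------
// Reaction network (rates mM/min, referenced to cell volume)
// r12 = LDH (pyruvate -> lactate positive), r18 = PDH (>= 0),
// r21 = MCT lactate-proton symport (positive = export).
// ---------------------------------------------------------------------------
static void reaction_rates_phi(const double* s, const LocalEnv& env,
                               const Params& p, double phi, double* r) {

  // r1 GLUT facilitated diffusion (reversible)
  r[0] = p.get(P_vmax_glut) * s[P_GLUT] *
         (mm(env.glc, p.get(P_km_glut)) - mm(s[GLC_I], p.get(P_km_glut)));
  // r2 hexokinase, G6P feedback inhibition
  r[1] = p.get(P_vmax_hk) * s[P_HK] * mm(s[GLC_I], p.get(P_km_hk)) *
         mm(s[ATP], p.get(P_km_atp_use)) * rep(s[G6P], p.get(P_ki_hk_g6p), 2.0);
  // r3 PGI
  r[2] = p.get(P_k_pgi) * (s[G6P] - s[F6P] / p.get(P_keq_pgi));
  // r4 PFK: pH-modulated limiting step; AMP activates, ATP and citrate
  // inhibit (classic allosteric control, gives the Pasteur and
  // glucose-sparing effects)
  {
    double act = p.get(P_pfk_amp_base) +
                 (1.0 - p.get(P_pfk_amp_base)) * hill(s[AMP], p.get(P_km_pfk_amp), 2.0);
    r[3] = p.get(P_vmax_pfk) * s[P_PFK] * mm(s[F6P], p.get(P_km_pfk)) *
           mm(s[ATP], p.get(P_km_atp_use)) * phi * act *
           rep(s[ATP], p.get(P_ki_pfk_atp), 4.0) *
           rep(s[CIT], p.get(P_ki_pfk_cit), 2.0) *
           rep(s[LAC_I], p.get(P_ki_pfk_lac), 2.0);
  }
  // r5 aldolase, r6 TPI
  r[4] = p.get(P_k_ald) * (s[F16BP] - s[DHAP] * s[GAP] / p.get(P_keq_ald));
  r[5] = p.get(P_k_tpi) * (s[DHAP] - s[GAP] / p.get(P_keq_tpi));
  // r7 GAPDH (NAD+ and Pi dependent)
  r[6] = p.get(P_k_gapdh) *
         (s[GAP] * s[NAD_C] * mm(s[PI], p.get(P_km_gapdh_pi)) -
          s[BPG13] * s[NADH_C] / p.get(P_keq_gapdh));
  // r8 PGK (ATP generating)
  r[7] = p.get(P_k_pgk) * (s[BPG13] * s[ADP] - s[PG3] * s[ATP] / p.get(P_keq_pgk));
  // r9 PGM, r10 enolase
  r[8] = p.get(P_k_pgm) * (s[PG3] - s[PG2] / p.get(P_keq_pgm));
  r[9] = p.get(P_k_eno) * (s[PG2] - s[PEP] / p.get(P_keq_eno));
  // r11 pyruvate kinase (ATP generating)
  r[10] = p.get(P_vmax_pk) * mm(s[PEP], p.get(P_km_pk_pep)) *
          mm(s[ADP], p.get(P_km_pk_adp));
  // r12 LDH: reversible Michaelis-Menten (near-equilibrium enzyme); sign
  // follows the thermodynamic direction
  r[11] = p.get(P_k_ldh) * s[P_LDH] *
          (s[PYR] * s[NADH_C] - s[LAC_I] * s[NAD_C] / p.get(P_keq_ldh)) /
          (1.0 + s[PYR] / p.get(P_km_ldh_pyr) + s[LAC_I] / p.get(P_km_ldh_lac));
  // r13 glycogen synthesis (capacity capped), r14 glycogenolysis
  r[12] = p.get(P_vmax_gys) * mm(s[G6P], p.get(P_km_gys_g6p)) *
          rep(s[GLY], p.get(P_gly_cap), 4.0);
  r[13] = p.get(P_vmax_gp) * mm(s[GLY], p.get(P_km_gp_gly)) *
          rep(s[G6P], p.get(P_ki_gp_g6p), 2.0);
  // r15 ATP demand (maintenance + biosynthesis); AMPK suppresses the
  // biosynthetic share under energy stress
  r[14] = p.get(P_vmax_atpase) * mm(s[ATP], p.get(P_km_atpase)) *
          (1.0 - p.get(P_ampk_demand_w) *
                 hill(s[P_AMPK], p.get(P_km_ampk_demand), 2.0));
  // r16 adenylate kinase 2 ADP <-> ATP + AMP
  r[15] = p.get(P_k_ak) * (s[ADP] * s[ADP] - s[ATP] * s[AMP] / p.get(P_keq_ak));
  // r17 malate-aspartate shuttle (lumped, toward mitochondria)
  r[16] = p.get(P_vmax_shuttle) * mm(s[NADH_C], p.get(P_km_shuttle_nadhc)) *
          mm(s[NAD_M], p.get(P_km_shuttle_nadm));
  // r18 PDH (irreversible; PDK and acetyl-CoA inhibit; pyruvate relieves
  // the PDK block, the classic feed-forward activation)
  {
    double pdk_eff = s[P_PDK] * rep(s[PYR], p.get(P_ki_pdk_pyr), 4.0);
    double v = p.get(P_vmax_pdh) * s[P_PDH] *
               rep(pdk_eff, p.get(P_ki_pdh_pdk), 2.0) *
               rep(s[ACCOA], p.get(P_ki_pdh_accoa), 2.0) *
               mm(s[PYR], p.get(P_km_pdh_pyr)) * mm(s[NAD_M], p.get(P_km_nadm));
    r[17] = (v > 0.0) ? v : 0.0;
  }
  // r19 citrate synthase (NADH-inhibited), r20 aconitase
  r[18] = p.get(P_k_cs) * s[ACCOA] * s[OAA] *
          rep(s[NADH_M], p.get(P_ki_cs_nadh), 2.0);
  r[19] = p.get(P_k_aco) * (s[CIT] - s[ICIT] / p.get(P_keq_aco));
  // r21 MCT: lactic-acid symport on the lactate*proton product gradient
  {
    double pi_prod = s[LAC_I] * s[H_I];
    double pe_prod = env.lac * env.h;
    r[20] = p.get(P_vmax_mct) * s[P_MCT] *
            (mm(pi_prod, p.get(P_km_mct)) - mm(pe_prod, p.get(P_km_mct)));
  }
  // r22 ETC complex I..IV + ATP synthase (NADH branch); oxygen dependent,
  // ADP-limited (respiratory control)
  r[21] = p.get(P_vmax_etc) * mm(s[NADH_M], p.get(P_km_etc_nadh)) *
          mm(env.o2, p.get(P_km_etc_o2)) * mm(s[ADP], p.get(P_km_etc_adp));
  // r23 intracellular proton buffering / pH regulation (free-H basis)
  {
    double h_ref = std::pow(10.0, -p.get(P_ph_i_ref)) * 1e3;
    r[22] = p.get(P_k_buf_i) * (h_ref - s[H_I]);
  }
  // r24 ETC (FADH2 branch)
  r[23] = p.get(P_vmax_etc2) * mm(s[FADH2], p.get(P_km_etc_fadh2)) *
          mm(env.o2, p.get(P_km_etc_o2)) * mm(s[ADP], p.get(P_km_etc_adp));
  // r25..r30 TCA cycle
  r[24] = p.get(P_k_idh) * s[ICIT] * mm(s[NAD_M], p.get(P_km_nadm));
  r[25] = p.get(P_k_kgdh) * s[AKG] * mm(s[NAD_M], p.get(P_km_nadm));
  r[26] = p.get(P_k_scs) * s[SUCCOA] * mm(s[ADP], p.get(P_km_scs_adp));
  r[27] = p.get(P_k_sdh) * s[SUC] * mm(s[FAD], p.get(P_km_sdh_fad));
  r[28] = p.get(P_k_fh) * (s[FUM] - s[MAL] / p.get(P_keq_fh));
  // MDH: thermodynamically unfavourable forward step, kept going by citrate
  // synthase draining OAA; modelled as OAA-product-inhibited (non-stiff form)
  r[29] = p.get(P_k_mdh) * s[MAL] * mm(s[NAD_M], p.get(P_km_nadm)) *
          rep(s[OAA], p.get(P_km_mdh_oaa), 1.0);

  for (int i = 0; i < N_REACTIONS; ++i) {
    if (!std::isfinite(r[i]))
      Rcpp::stop("non-finite reaction rate r" + std::to_string(i + 1));
  }
}

static inline double phi_of(const double* s, const LocalEnv& env,
                            const Params& p) {
  return ph_factor(ph_of(s[H_I]), p) * ph_factor(ph_of(env.h), p);
}

void reaction_rates(const double* s, const LocalEnv& env, const Params& p,
                    double* r) {
  reaction_rates_phi(s, env, p, phi_of(s, env, p), r);
}

// phi (pH inhibition) is held constant over one metabolism step: pH moves on
// a much slower timescale than the metabolite substeps.
// racc/w: optional accumulation of stage rates (RK4 quadrature weights), so
// reported interval-average fluxes are exactly consistent with the state
// update.
static void network_rhs_phi(const double* s, const LocalEnv& env,
                            const Params& p, double gamma,
                            const double* gene_noise, double phi, double* ds,
                            double* racc = 0, double w = 0.0) {
  double r[N_REACTIONS];
  reaction_rates_phi(s, env, p, phi, r);
  if (racc)
    for (int i = 0; i < N_REACTIONS; ++i) racc[i] += w * r[i];
  const double v1 = r[0], v2 = r[1], v3 = r[2], v4 = r[3], v5 = r[4],
               v6 = r[5], v7 = r[6], v8 = r[7], v9 = r[8], v10 = r[9],
               v11 = r[10], v12 = r[11], v13 = r[12], v14 = r[13],
               v15 = r[14], v16 = r[15], v17 = r[16], v18 = r[17],
               v19 = r[18], v20 = r[19], v21 = r[20], v22 = r[21],
               v23 = r[22], v24 = r[23], v25 = r[24], v26 = r[25],
               v27 = r[26], v28 = r[27], v29 = r[28], v30 = r[29];

  for (int i = 0; i < N_STATE; ++i) ds[i] = 0.0;

  ds[GLC_I] = v1 - v2;
  ds[G6P]   = v2 - v3 - v13 + v14;
  ds[F6P]   = v3 - v4;
  ds[F16BP] = v4 - v5;
  ds[DHAP]  = v5 - v6;
  ds[GAP]   = v5 + v6 - v7;
  ds[BPG13] = v7 - v8;
  ds[PG3]   = v8 - v9;
  ds[PG2]   = v9 - v10;
  ds[PEP]   = v10 - v11;
  ds[PYR]   = v11 - v12 - v18;
  ds[LAC_I] = v12 - v21;
  ds[H_I]   = (v12 - v21) / p.get(P_buffer_ratio) + v23;
  ds[GLY]   = v13 - v14;
  ds[ACCOA] = v18 - v19;
  ds[CIT]   = v19 - v20;
  ds[ICIT]  = v20 - v25;
  ds[AKG]   = v25 - v26;
  ds[SUCCOA] = v26 - v27;
  ds[SUC]   = v27 - v28;
  ds[FUM]   = v28 - v29;
  ds[MAL]   = v29 - v30;
  ds[OAA]   = v30 - v19;

  double atp_gain = v8 + v11 + v27 + p.get(P_p_o_nadh) * v22 +
                    p.get(P_p_o_fadh2) * v24 + v16;
  double atp_use = v2 + v4 + v15 + p.get(P_atp_per_gys) * v13;
  ds[ATP] = atp_gain - atp_use;
  ds[ADP] = atp_use - (v8 + v11 + v27 + p.get(P_p_o_nadh) * v22 +
                       p.get(P_p_o_fadh2) * v24) - 2.0 * v16;
  ds[AMP] = v16;
  ds[PI]  = v15 - v7 + p.get(P_k_pi_relax) * (p.get(P_pi_ref) - s[PI]);

  ds[NADH_C] = v7 - v12 - v17;
  ds[NAD_C]  = -ds[NADH_C];
  ds[NADH_M] = v17 + v18 + v25 + v26 + v30 - v22;
  ds[NAD_M]  = -ds[NADH_M];
  ds[FADH2]  = v28 - v24;
  ds[FAD]    = -ds[FADH2];

  // --- gene regulation: relaxation toward environment-dependent drives ---
  const double hifp = s[P_HIF1A], mycp = s[P_MYC], ampkp = s[P_AMPK];
  const double kh = p.get(P_kh_gene), nh = p.get(P_nh_gene);
  const double h_hif = hill(hifp, kh, nh);
  const double h_myc = hill(mycp, p.get(P_km_myc), 2.0);

  double drive[N_GENES];
  drive[0] = p.get(P_hif_a0) +
             p.get(P_hif_alac) * hill(s[LAC_I], p.get(P_km_hif_lac), 2.0) +
             p.get(P_hif_ao2) * rep(env.o2, p.get(P_km_hif_o2), 2.0);
  drive[1] = p.get(P_ldh_b0) + p.get(P_ldh_bh) * h_hif + p.get(P_ldh_bm) * h_myc;
  {
    double w = p.get(P_pdh_ampk_w);
    drive[2] = p.get(P_pdh_b0) + p.get(P_pdh_bh) * rep(hifp, kh, nh) *
               ((1.0 - w) + w * hill(ampkp, 1.0, 2.0));
  }
  drive[3] = p.get(P_pdk_b0) + p.get(P_pdk_bh) * h_hif;
  drive[4] = p.get(P_glut_b0) + p.get(P_glut_bh) * h_hif + p.get(P_glut_bm) * h_myc;
  drive[5] = p.get(P_mct_b0) + p.get(P_mct_bh) * h_hif;
  drive[6] = p.get(P_hk_b0) + p.get(P_hk_bh) * h_hif + p.get(P_hk_bm) * h_myc;
  drive[7] = p.get(P_pfk_b0) + p.get(P_pfk_bh) * h_hif + p.get(P_pfk_bm) * h_myc;
  drive[8] = p.get(P_myc_b0);
  {
    double ratio = (s[ATP] > 1e-9) ? s[ADP] / s[ATP] : 1e3;
    drive[9] = p.get(P_ampk_b0) +
               p.get(P_ampk_be) * hill(ratio, p.get(P_km_ampk_adp), 2.0);
  }

  for (int g = 0; g < N_GENES; ++g) {
    double dg = (g == 0) ? p.get(P_d_hif) : p.get(P_d_gene);
    double noise = gene_noise ? gene_noise[g] : 0.0;
    ds[G_HIF1A + g] = gamma * dg * (drive[g] - s[G_HIF1A + g]) + noise;
    ds[P_HIF1A + g] = p.get(P_k_translate) * s[G_HIF1A + g] -
                      p.get(P_d_prot) * s[P_HIF1A + g];
  }
}

void network_rhs(const double* s, const LocalEnv& env, const Params& p,
                 double gamma, const double* gene_noise, double* ds) {
  network_rhs_phi(s, env, p, gamma, gene_noise, phi_of(s, env, p), ds);
}

// ---------------------------------------------------------------------------
// RK4 with halving on positivity breach
// ---------------------------------------------------------------------------
static bool rk4_once(double* s, const LocalEnv& env, const Params& p,
                     double gamma, const double* noise, double phi, double h,
                     double* snew, double* racc) {
  double k1[N_STATE], k2[N_STATE], k3[N_STATE], k4[N_STATE], tmp[N_STATE];
  network_rhs_phi(s, env, p, gamma, noise, phi, k1, racc, h / 6.0);
  for (int i = 0; i < N_STATE; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
  network_rhs_phi(tmp, env, p, gamma, noise, phi, k2, racc, h / 3.0);
  for (int i = 0; i < N_STATE; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
  network_rhs_phi(tmp, env, p, gamma, noise, phi, k3, racc, h / 3.0);
  for (int i = 0; i < N_STATE; ++i) tmp[i] = s[i] + h * k3[i];
  network_rhs_phi(tmp, env, p, gamma, noise, phi, k4, racc, h / 6.0);
  bool ok = true;
  for (int i = 0; i < N_STATE; ++i) {
    snew[i] = s[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(snew[i])) return false;
    // tolerate small undershoots (clipped later); halve only on real breaches
    if (snew[i] < -(1e-6 + 0.1 * std::fabs(s[i]))) { ok = false; ++msx_breach_var[i]; }
    // halve on suspiciously large single-step jumps (stiff oscillation guard)
    if (std::fabs(snew[i] - s[i]) > 1.0 * (std::fabs(s[i]) + 0.01)) ok = false;
  }
  return ok;
}

long msx_halve_count = 0;
long msx_step_count = 0;
long msx_breach_var[N_STATE] = {0};

static void integrate_interval(double* s, const LocalEnv& env, const Params& p,
                               double gamma, const double* noise, double phi,
                               double dt, double* racc) {
  int max_depth = 4;
  double remaining = dt;
  double h = dt;
  int depth = 0;
  double snew[N_STATE], racc_try[N_REACTIONS];
  while (remaining > 1e-12) {
    if (h > remaining) h = remaining;
    for (int i = 0; i < N_REACTIONS; ++i) racc_try[i] = 0.0;
    bool ok = rk4_once(s, env, p, gamma, noise, phi, h, snew, racc_try);
    if (!ok && depth < max_depth) {
      ++msx_halve_count;
      h *= 0.5;
      ++depth;
      continue;
    }
    if (!ok) {
      // at minimum substep: accept with clipping (guards tiny undershoots)
      for (int i = 0; i < N_STATE; ++i)
        if (!std::isfinite(snew[i]))
          Rcpp::stop("metabolism integrator diverged (non-finite state)");
    }
    for (int i = 0; i < N_STATE; ++i) s[i] = (snew[i] > 0.0) ? snew[i] : 0.0;
    if (racc)
      for (int i = 0; i < N_REACTIONS; ++i) racc[i] += racc_try[i];
    remaining -= h;
  }
}

void step_metabolism(double* s, const LocalEnv& env, const Params& p,
                     double gamma, double dt_min, double noise_amp,
                     uint64_t seed, uint64_t cell_id, uint64_t step_index,
                     double* r_avg, double* exch) {
  // gene noise: additive Gaussian on the gene RHS, constant over the step
  // (Euler-Maruyama treatment); amplitude noise_amp x unit expression scale.
  // One stream key per (seed, cell, step); paired Box-Muller draws.
  double noise[N_GENES];
  if (noise_amp > 0.0) {
    const double inv53 = 1.0 / 9007199254740992.0;
    uint64_t key = mix4(seed, cell_id, step_index, 0x9E3779B97F4AULL);
    double amp = noise_amp / std::sqrt(dt_min);
    for (int g = 0; g < N_GENES; g += 2) {
      double u1 = ((splitmix64(key + (uint64_t)g + 1) >> 11) + 0.5) * inv53;
      double u2 = ((splitmix64(key + (uint64_t)g + 2) >> 11) + 0.5) * inv53;
      double rad = std::sqrt(-2.0 * std::log(u1));
      double a = 2.0 * M_PI * u2;
      noise[g] = amp * rad * std::cos(a);
      if (g + 1 < N_GENES) noise[g + 1] = amp * rad * std::sin(a);
    }
  } else {
    for (int g = 0; g < N_GENES; ++g) noise[g] = 0.0;
  }

  ++msx_step_count;
  double phi = phi_of(s, env, p);
  for (int i = 0; i < N_REACTIONS; ++i) r_avg[i] = 0.0;
  integrate_interval(s, env, p, gamma, noise, phi, dt_min, r_avg);
  for (int i = 0; i < N_REACTIONS; ++i) r_avg[i] /= dt_min;

  // exchange with the environment (cell-volume referenced, + = released)
  double o2_cons = 0.5 * (r_avg[21] + r_avg[23]); // 0.5 O2 per ETC turnover
  exch[0] = -o2_cons;
  exch[1] = -r_avg[0];
  exch[2] = r_avg[20];
  exch[3] = r_avg[20] / p.get(P_buffer_ratio);
}
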