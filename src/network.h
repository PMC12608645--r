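#ifndef MSX_NETWORK_H
#define MSX_NETWORK_H

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

// ---------------------------------------------------------------------------
// State layout: 53 variables per cell.
//   0..32  metabolites (mM; free protons for H_I; glucosyl units for GLY)
//  33..42  gene expressions (a.u.)
//  43..52  protein products of the ten genes (a.u., scale enzyme Vmax)
// ---------------------------------------------------------------------------
enum StateIdx {
  GLC_I = 0, G6P, F6P, F16BP, DHAP, GAP, BPG13, PG3, PG2, PEP,
  PYR, LAC_I, H_I, GLY,
  ACCOA, CIT, ICIT, AKG, SUCCOA, SUC, FUM, MAL, OAA,
  ATP, ADP, AMP, PI,
  NAD_C, NADH_C, NAD_M, NADH_M, FAD, FADH2,
  G_HIF1A, G_LDH, G_PDH, G_PDK, G_GLUT, G_MCT, G_HK, G_PFK, G_MYC, G_AMPK,
  P_HIF1A, P_LDH, P_PDH, P_PDK, P_GLUT, P_MCT, P_HK, P_PFK, P_MYC, P_AMPK,
  N_STATE // 53
};

static const int N_GENES = 10;
static const int N_REACTIONS = 30;

// Local environment seen by one cell (all mM; proton as free H+).
struct LocalEnv {
  double o2;
  double glc;
  double lac;
  double h;
};

// Named kinetic parameters; filled from a named vector (strict matching).
struct Params {
  std::vector<double> v;
  // index-by-name resolved once at load
  double get(int i) const { return v[i]; }
};

const std::vector<std::string>& param_names();
Params params_from_named(const Rcpp::NumericVector& x);

const std::vector<std::string>& state_names();

// All 30 reaction rates (mM/min, cell-volume referenced) given state + env.
void reaction_rates(const double* s, const LocalEnv& env, const Params& p,
                    double* r);

// Full RHS (d state / d min). noise: per-gene additive term (a.u./min)
// held constant over the step (Euler-Maruyama drift treatment).
void network_rhs(const double* s, const LocalEnv& env, const Params& p,
                 double gamma, const double* gene_noise, double* ds);

// One metabolism step (RK4 with halving on positivity breach).
// Returns interval-average reaction rates in r_avg (length N_REACTIONS).
// exch (length 4): average exchange rates with the environment, mM/min,
// cell-volume referenced, sign: positive = released to environment
// (order: oxygen, glucose, lactate, proton-free-H).
void step_metabolism(double* s, const LocalEnv& env, const Params& p,
                     double gamma, double dt_min, double noise_amp,
                     uint64_t seed, uint64_t cell_id, uint64_t step_index,
                     double* r_avg, double* exch);

// pH inhibition factor in [0,1], == 1 at pH >= 7.4.
double ph_factor(double ph, const Params& p);

// Counter-based RNG helpers (order-independent per-cell streams).
double msx_runif1(uint64_t seed, uint64_t cell_id, uint64_t ctr1, uint64_t ctr2);
double msx_rnorm1(uint64_t seed, uint64_t cell_id, uint64_t ctr1, uint64_t ctr2);

// Integrator diagnostics (cumulative; reset by msx_halve_stats()).
extern long msx_halve_count;
extern long msx_step_count;
extern long msx_breach_var[];

#endif
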