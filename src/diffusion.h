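#ifndef MSX_DIFFUSION_H
#define MSX_DIFFUSION_H

#include <vector>

// One Peaceman-Rachford ADI step of the 2D diffusion equation with optional
// volumetric source (mM/min). Unconditionally stable, second order in time.
// bc_kind: 0 = Dirichlet (boundary ring clamped to bc_value after every half
// sweep), 1 = zero-flux Neumann (reflecting). Returns clipped mass (mM*voxel)
// removed by the negativity floor when applying the source.
double adi_step(std::vector<double>& c, int nx, int ny, double D, double dt_min,
                double h_um, int bc_kind, double bc_value,
                const double* source /* may be null */);

#endif
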