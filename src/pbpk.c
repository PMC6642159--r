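/* Right-hand side of the circadian whole-body talinolol model, compiled
 * for use with deSolve (func = "deriv_talpbpk", dllname = "chronopgp").
 *
 * States (amounts, ug):
 *   y0 gut lumen, y1 ileum mucosa, y2 plasma, y3 liver,
 *   y4 cumulative urine, y5 cumulative feces
 *
 * Parameter vector (length 45, packed by pack_pbpk_parms() on the R side):
 *   [0] ka  [1] k_ib  [2] k_pl_li  [3] k_li_pl  [4] zt_dose
 *   then four circadian-rate blocks of 10 doubles each
 *   (pgp_ileum, pgp_liver, renal, intestinal):
 *   mean_rate, then 3 x {rel_amplitude, period_h, acrophase_h}
 *   (unused harmonic slots have rel_amplitude = 0).
 */
#include <math.h>

#ifndef M_PI
#define M_PI 3.14159265358979323846
#endif

#define NPARMS 45
static double parms[NPARMS];

void init_talpbpk(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double crate(const double *b, double zt)
{
    double mod = 1.0;
    int k;
    for (k = 0; k < 3; k++) {
        double amp = b[1 + 3 * k];
        double per = b[2 + 3 * k];
        double phi = b[3 + 3 * k];
        if (amp > 0.0 && per > 0.0)
            mod += amp * cos(2.0 * M_PI * (zt - phi) / per);
    }
    return b[0] * mod;
}

void deriv_talpbpk(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double zt = fmod(parms[4] + *t, 24.0);
    double rI = crate(parms + 5, zt);   /* ileum P-gp efflux -> lumen   */
    double rL = crate(parms + 15, zt);  /* hepatic P-gp (biliary) -> lumen */
    double rR = crate(parms + 25, zt);  /* renal elimination from plasma */
    double rF = crate(parms + 35, zt);  /* intestinal (fecal) from lumen */
    double ka = parms[0], kib = parms[1], kpl = parms[2], klp = parms[3];

    ydot[0] = -ka * y[0] - rF * y[0] + rI * y[1] + rL * y[3];
    ydot[1] = ka * y[0] - rI * y[1] - kib * y[1];
    ydot[2] = kib * y[1] - kpl * y[2] + klp * y[3] - rR * y[2];
    ydot[3] = kpl * y[2] - klp * y[3] - rL * y[3];
    ydot[4] = rR * y[2];
    ydot[5] = rF * y[0];
}
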