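/* Right-hand side of the erythropoietic feedback circuit, in the form
 * expected by deSolve's compiled-model interface.
 *
 * State:  y[0] = P (progenitors), y[1] = Q (ProE/precursors),
 *         y[2] = R (RBC), y[3] = E (Epo).
 * Parameters (order fixed, see .parms_vector() on the R side):
 *   0 influx_F   1 gmin     2 delta_g  3 Ka    4 na
 *   5 Ks         6 ns       7 k_P      8 k_Q   9 delta_R
 *  10 beta_E    11 delta_E 12 K_E     13 m_E  14 c_O2
 *  15 t_onset   16 ramp_tau 17 alpha_min 18 ramp_shape (0 linear, 1 cosine)
 *  19 epo_source (constant exogenous Epo input)
 */
#include <R.h>
#include <math.h>

static double parms[20];

void erythro_init(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, parms);
}

/* Overflow-safe Hill: 1/(1+(K/x)^n); returns 0 at x<=0, handles x<<K and
 * x>>K without intermediate overflow of x^n. */
static double hill_c(double x, double K, double n)
{
    double r;
    if (x <= 0.0) return 0.0;
    r = pow(K / x, n);
    return 1.0 / (1.0 + r);
}

static double alpha_c(double t)
{
    double t0 = parms[15], tau = parms[16], amin = parms[17];
    double frac;
    if (t < t0) return 1.0;
    if (tau <= 0.0 || t >= t0 + tau) return amin;
    frac = (t - t0) / tau;
    if (parms[18] > 0.5)                     /* cosine (smooth) ramp */
        frac = 0.5 * (1.0 - cos(M_PI * frac));
    return 1.0 - (1.0 - amin) * frac;
}

void erythro_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double P = y[0], Q = y[1], R = y[2], E = y[3];
    double g  = parms[1] + parms[2] * hill_c(E, parms[3], parms[4]);
    double s  = hill_c(E, parms[5], parms[6]);
    double pO2 = parms[14] * alpha_c(*t) * R;

    ydot[0] = parms[0] + (g - parms[7]) * P;
    ydot[1] = parms[7] * P - parms[8] * Q;
    ydot[2] = parms[8] * s * Q - parms[9] * R;
    ydot[3] = parms[10] * (1.0 - hill_c(pO2, parms[12], parms[13]))
              + parms[19] - parms[11] * E;
}
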