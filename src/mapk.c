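/* Compiled rate equations for the two MAPK cascade models, plugged into
 * deSolve through its dllname/initfunc interface.  Parameter vectors are
 * assembled on the R side in a fixed order (see R/mapk-models.R); the
 * layouts here must stay in sync with .mapk_egf_parm_vector() and
 * .mapk_egf_ngf_parm_vector(). */

#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* Michaelis-Menten building blocks: activation of substrate S by modifier M
 * with rate constant k and Michaelis constant K, and first-order saturable
 * decay with maximal rate V. */
static double ma(double k, double K, double S, double M)
{
    return k * S * M / (K + S);
}

static double m0(double V, double K, double S)
{
    return V * S / (K + S);
}

/* --- EGF-driven three-tier cascade (aRAF, aMEK, aERK) ---------------------
 * parms layout (20):
 *  0 k_f1   1 K_mf1   2 V_m1   3 K_m1
 *  4 k_f2   5 K_mf2   6 V_m2   7 K_m2
 *  8 k_f3   9 K_mf3  10 V_m3  11 K_m3
 * 12 k_r1  13 K_mr1  14 k_r2  15 K_mr2
 * 16 RAF_TOT  17 MEK_TOT  18 ERK_TOT  19 EGF
 */
static double p_egf[20];

void initmod_mapk_egf(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, p_egf);
}

void derivs_mapk_egf(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double *p = p_egf;
    double iRAF = p[16] - y[0];
    double iMEK = p[17] - y[1];
    double iERK = p[18] - y[2];
    double EGF = p[19];

    ydot[0] = ma(p[0], p[1], iRAF, EGF)
        - ma(p[12], p[13], y[0], y[2])
        - m0(p[2], p[3], y[0]);
    ydot[1] = ma(p[4], p[5], iMEK, y[0])
        - ma(p[14], p[15], y[1], y[2])
        - m0(p[6], p[7], y[1]);
    ydot[2] = ma(p[8], p[9], iERK, y[1])
        - m0(p[10], p[11], y[2]);
}

/* --- EGF/NGF cascade with transient RAS input -----------------------------
 * parms layout (31):
 *  0 k_f11  1 K_mf11  2 k_r12  3 K_mr12
 *  4 k_f13  5 K_mf13  6 k_f14  7 K_mf14
 *  8 V_m1   9 K_m1
 * 10 k_f21 11 K_mf21 12 k_f22 13 K_mf22
 * 14 V_m2  15 K_m2
 * 16 k_f31 17 K_mf31 18 k_f32 19 K_mf32
 * 20 V_m3  21 K_m3
 * 22 kd_egf 23 kd_ngf
 * 24 RAF_TOT 25 MEK_TOT 26 ERK_TOT
 * 27 b_e  28 b_n  29 EGF  30 NGF
 */
static double p_en[31];

void initmod_mapk_egf_ngf(void (*odeparms)(int *, double *))
{
    int n = 31;
    odeparms(&n, p_en);
}

static double ras_pulse(double L, double kd, double t)
{
    return (L / (1.0 + L)) * pow(t, 5.0) * exp(-kd * t);
}

void derivs_mapk_egf_ngf(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    const double *p = p_en;
    double iRAF = p[24] - y[0];
    double iMEK = p[25] - y[1];
    double iERK = p[26] - y[2];
    double be = p[27], bn = p[28];
    double ras_egf = ras_pulse(p[29], p[22], *t);
    double ras_ngf = ras_pulse(p[30], p[23], *t);

    ydot[0] = be * (ma(p[0], p[1], iRAF, ras_egf)
                    - ma(p[2], p[3], y[0], y[2]))
        + bn * (ma(p[4], p[5], iRAF, ras_ngf)
                + ma(p[6], p[7], iRAF, y[2]))
        - m0(p[8], p[9], y[0]);
    ydot[1] = ma(p[10], p[11], iMEK, y[0])
        - ma(p[12], p[13], y[1], y[2])
        - m0(p[14], p[15], y[1]);
    ydot[2] = ma(p[16], p[17], iERK, y[1])
        + bn * ma(p[18], p[19], iERK, y[0])
        - m0(p[20], p[21], y[2]);
}

static const R_CMethodDef CEntries[] = {
    {"derivs_mapk_egf",      (DL_FUNC) &derivs_mapk_egf,      6},
    {"initmod_mapk_egf",     (DL_FUNC) &initmod_mapk_egf,     1},
    {"derivs_mapk_egf_ngf",  (DL_FUNC) &derivs_mapk_egf_ngf,  6},
    {"initmod_mapk_egf_ngf", (DL_FUNC) &initmod_mapk_egf_ngf, 1},
    {NULL, NULL, 0}
};

void R_init_mrafit(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
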