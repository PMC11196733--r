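/* Compiled right-hand sides for the colitis ODE variants, in the calling
 * convention deSolve expects for dllname-based models.  Integration is
 * performed segment-wise over piecewise-constant treatment protocols, so the
 * current input concentration is passed as an ordinary parameter and each
 * RHS is autonomous within a segment.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

/* Smooth saturation far beyond any data scale (~1e2): damps the
 * exponential blow-up of hopeless parameter draws during multi-start
 * optimization so the solver returns huge but finite values with a usable
 * gradient instead of overflowing. Inactive (factor ~ 1) below Y_BIG. */
#define Y_BIG 1e6

static void clamp_growth(int n, const double *y, double *ydot)
{
    for (int i = 0; i < n; i++) {
        double r = y[i] / Y_BIG;
        ydot[i] /= 1.0 + r * r;
    }
}

/* murine parms: k_heal, k_turnB, k_turnM, k_turnN, k_turnT, k_turnE,
 *               input (DSS %), wMac, wNeutr, wTcell
 * w* flags: 0 -> driver is the DSS input, 1 -> driver is the Damage state.
 * States: Damage, healedMucosa, Bcell, Mac, Neutr, Tcell [, Epi]
 */
static double parms_murine[10];

void colitisdyn_init_murine(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms_murine);
}

void colitisdyn_derivs_murine(int *neq, double *t, double *y, double *ydot,
                              double *yout, int *ip)
{
    const double k_heal = parms_murine[0];
    const double kB = parms_murine[1], kM = parms_murine[2];
    const double kN = parms_murine[3], kT = parms_murine[4];
    const double kE = parms_murine[5];
    const double u = parms_murine[6];

    const double damage = y[0], healed = y[1];
    const double drvM = parms_murine[7] > 0.5 ? damage : u;
    const double drvN = parms_murine[8] > 0.5 ? damage : u;
    const double drvT = parms_murine[9] > 0.5 ? damage : u;

    ydot[0] = u - k_heal * damage;
    ydot[1] = k_heal * damage;
    ydot[2] = (kB * healed - 1.0 / kB) * y[2];
    ydot[3] = (kM * drvM - 1.0 / kM) * y[3];
    ydot[4] = (kN * drvN - 1.0 / kN) * y[4];
    ydot[5] = (kT * drvT - 1.0 / kT) * y[5];
    if (*neq > 6)                       /* extended variant: epithelium */
        ydot[6] = (kE - (1.0 / kE) * u) * y[6];
    clamp_growth(*neq, y, ydot);
}

/* human parms: k_cue, k_act, k_res, k_turnB, k_turnM, k_turnN, k_turnT,
 *              k_turnE
 * States: Cue, ActiveIBD, Resolution, Bcell, Mac, Neutr, Tcell, Epi
 */
static double parms_human[8];

void colitisdyn_init_human(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms_human);
}

void colitisdyn_derivs_human(int *neq, double *t, double *y, double *ydot,
                             double *yout, int *ip)
{
    const double k_cue = parms_human[0];
    const double k_act = parms_human[1], k_res = parms_human[2];
    const double kB = parms_human[3], kM = parms_human[4];
    const double kN = parms_human[5], kT = parms_human[6];
    const double kE = parms_human[7];

    const double cue = y[0], act = y[1], res = y[2];

    ydot[0] = -k_cue * cue;
    ydot[1] = k_act - (1.0 / k_act) * act;
    ydot[2] = k_res - (1.0 / k_res) * res;
    ydot[3] = (kB * res - 1.0 / kB) * y[3];
    ydot[4] = (kM * act - 1.0 / kM) * y[4];
    ydot[5] = (kN * cue - 1.0 / kN) * y[5];
    ydot[6] = (kT * act - 1.0 / kT) * y[6];
    ydot[7] = (kE - (1.0 / kE) * cue) * y[7];
    clamp_growth(*neq, y, ydot);
}

static const R_CMethodDef cMethods[] = {
    {"colitisdyn_init_murine",   (DL_FUNC) &colitisdyn_init_murine,   1},
    {"colitisdyn_derivs_murine", (DL_FUNC) &colitisdyn_derivs_murine, 6},
    {"colitisdyn_init_human",    (DL_FUNC) &colitisdyn_init_human,    1},
    {"colitisdyn_derivs_human",  (DL_FUNC) &colitisdyn_derivs_human,  6},
    {NULL, NULL, 0}
};

void R_init_colitisdyn(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
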