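/* Bergman minimal model right-hand side for deSolve.
 *
 * State y = (G, X, I, eps); parameters
 *   parms = (p1, p2, p3, n, Ib, Gss, V1, u, Gm, literal)
 * with u the zero-order-held insulin infusion (mU/min), Gm the meal input
 * and literal != 0 selecting the verbatim printed equations
 * (dG has -p1*G and dI decays toward -Ib) instead of the deviation form
 * (dG has -p1*(G - Gss), dI decays toward +Ib).
 */

#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[10];

void glycoreg_init(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms);
}

void glycoreg_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double p1 = parms[0], p2 = parms[1], p3 = parms[2];
    const double n = parms[3], Ib = parms[4], Gss = parms[5];
    const double V1 = parms[6], u = parms[7], Gm = parms[8];
    const int literal = parms[9] != 0.0;
    const double G = y[0], X = y[1], I = y[2];

    ydot[0] = (literal ? -p1 * G : -p1 * (G - Gss))
              - X * (G - Gss) + Gm / V1;
    ydot[1] = -p2 * X + p3 * I;
    ydot[2] = (literal ? -n * (I + Ib) : -n * (I - Ib)) + u / V1;
    ydot[3] = Gss - G;
}

static const R_CMethodDef CEntries[] = {
    {"glycoreg_init",   (DL_FUNC) &glycoreg_init,   1},
    {"glycoreg_derivs", (DL_FUNC) &glycoreg_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_glycoreg(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
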