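/* Compiled right-hand side and Jacobian for the whole-body MMAE PBPK model.
 *
 * The system is linear except for the bilinear tubulin-binding term in the
 * tumor intracellular states, so the model is passed to the integrator as a
 * dense coefficient matrix A (built in R, see build_pbpk_system) plus a
 * single nonlinear correction +/- kon * Cfree * Cbound.
 *
 * State layout (0-based, must match R side):
 *   0..1    central plasma, central blood cells
 *   2..76   15 tissues x {plasma, bc, endothelial, interstitial, cellular}
 *   77..79  tumor extracellular, intracellular free, intracellular bound
 *   80      cumulative amount eliminated (pmol)
 *
 * parms = c(kon, as.vector(A))  with A in column-major order.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define N_STATE 81
#define I_FREE 78
#define I_BOUND 79
#define N_PARMS (1 + N_STATE * N_STATE)

static double parms[N_PARMS];

void mmae_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void mmae_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double kon = parms[0];
    const double *A = parms + 1;
    for (int i = 0; i < N_STATE; i++)
        ydot[i] = 0.0;
    for (int j = 0; j < N_STATE; j++) {
        const double yj = y[j];
        if (yj == 0.0) continue;
        const double *col = A + (size_t) N_STATE * j;
        for (int i = 0; i < N_STATE; i++)
            ydot[i] += col[i] * yj;
    }
    /* bilinear part of kon * Cfree * (Ctubulin - Cbound); the linear pieces
     * (kon*Ctubulin and koff) live in A */
    const double nl = kon * y[I_FREE] * y[I_BOUND];
    ydot[I_FREE] += nl;
    ydot[I_BOUND] -= nl;
}

void mmae_jac(int *neq, double *t, double *y, int *ml, int *mu,
              double *pd, int *nrowpd, double *yout, int *ip)
{
    const double kon = parms[0];
    const double *A = parms + 1;
    const int nr = *nrowpd;
    for (int j = 0; j < N_STATE; j++)
        for (int i = 0; i < N_STATE; i++)
            pd[i + (size_t) nr * j] = A[i + (size_t) N_STATE * j];
    pd[I_FREE + (size_t) nr * I_FREE] += kon * y[I_BOUND];
    pd[I_FREE + (size_t) nr * I_BOUND] += kon * y[I_FREE];
    pd[I_BOUND + (size_t) nr * I_FREE] -= kon * y[I_BOUND];
    pd[I_BOUND + (size_t) nr * I_BOUND] -= kon * y[I_FREE];
}

static const R_CMethodDef cMethods[] = {
    {"mmae_initmod", (DL_FUNC) &mmae_initmod, 1},
    {"mmae_derivs",  (DL_FUNC) &mmae_derivs,  6},
    {"mmae_jac",     (DL_FUNC) &mmae_jac,     9},
    {NULL, NULL, 0}
};

void R_init_mmaepbpk(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
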