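#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void lupsma_initmod(void (*odeparms)(int *, double *));
void lupsma_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);

/* deSolve looks these symbols up by name via getNativeSymbolInfo(); the
 * R_CMethodDef table keeps them registered and visible. */
static const R_CMethodDef CEntries[] = {
    {"lupsma_initmod", (DL_FUNC) &lupsma_initmod, 1},
    {"lupsma_derivs",  (DL_FUNC) &lupsma_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_lupsma(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
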