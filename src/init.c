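#include <R.h>
#include <R_ext/Rdynload.h>

void ccrm_initmod(void (*odeparms)(int *, double *));
void ccrm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"ccrm_initmod", (DL_FUNC) &ccrm_initmod, 1},
    {"ccrm_derivs",  (DL_FUNC) &ccrm_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_ccrmkin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* deSolve looks the symbols up by name at run time */
    R_useDynamicSymbols(dll, TRUE);
}
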