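#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void scgm_init(void (*odeparms)(int *, double *));
void scgm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);
void cscgm_init(void (*odeparms)(int *, double *));
void cscgm_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);
void cscgm_fast_init(void (*odeparms)(int *, double *));
void cscgm_fast_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"scgm_init",    (DL_FUNC) &scgm_init,    1},
    {"scgm_derivs",  (DL_FUNC) &scgm_derivs,  6},
    {"cscgm_init",   (DL_FUNC) &cscgm_init,   1},
    {"cscgm_derivs", (DL_FUNC) &cscgm_derivs, 6},
    {"cscgm_fast_init",   (DL_FUNC) &cscgm_fast_init,   1},
    {"cscgm_fast_derivs", (DL_FUNC) &cscgm_fast_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_scgm(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE);
}
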