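#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_cyclin_rhs(SEXP y, SEXP parms);
SEXP C_integrate_rk4(SEXP y0, SEXP times, SEXP parms, SEXP hmax,
                     SEXP ymax);

static const R_CallMethodDef callMethods[] = {
    {"C_cyclin_rhs",     (DL_FUNC) &C_cyclin_rhs,     2},
    {"C_integrate_rk4",  (DL_FUNC) &C_integrate_rk4,  5},
    {NULL, NULL, 0}
};

void R_init_cyclinpt(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
    R_forceSymbols(info, TRUE);
}
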