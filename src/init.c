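#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rcpp attribute export (RcppExports.cpp) */
extern SEXP _benthox_ecoevo_rk4(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                SEXP, SEXP, SEXP);

/* deSolve compiled-model routines (benthic_model.c) */
extern void benthox_o2_init(void (*odeparms)(int *, double *));
extern void benthox_o2_deriv(int *, double *, double *, double *, double *,
                             int *);
extern void benthox_o2_jac(int *, double *, double *, int *, int *,
                           double *, int *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"_benthox_ecoevo_rk4", (DL_FUNC) &_benthox_ecoevo_rk4, 10},
    {NULL, NULL, 0}
};

void R_init_benthox(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* deSolve resolves the model routines by name */
    R_useDynamicSymbols(dll, TRUE);
}
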