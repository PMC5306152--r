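#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_h5ds_attach(SEXP, SEXP, SEXP, SEXP);
SEXP C_h5ds_is_attached(SEXP, SEXP, SEXP, SEXP);
SEXP C_h5ds_is_scale(SEXP, SEXP);
SEXP C_h5ds_detach(SEXP, SEXP, SEXP, SEXP);
SEXP C_h5vl_write(SEXP, SEXP, SEXP);
SEXP C_h5vl_read(SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_h5ds_attach",      (DL_FUNC) &C_h5ds_attach,      4},
    {"C_h5ds_is_attached", (DL_FUNC) &C_h5ds_is_attached, 4},
    {"C_h5ds_is_scale",    (DL_FUNC) &C_h5ds_is_scale,    2},
    {"C_h5ds_detach",      (DL_FUNC) &C_h5ds_detach,      4},
    {"C_h5vl_write",       (DL_FUNC) &C_h5vl_write,       3},
    {"C_h5vl_read",        (DL_FUNC) &C_h5vl_read,        2},
    {NULL, NULL, 0}
};

void R_init_lfpsim(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
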