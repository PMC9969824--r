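#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_xtc_scan(SEXP);
extern SEXP C_xtc_read_frame(SEXP, SEXP);
extern SEXP C_xtc_write_frame(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP C_delaunay(SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_xtc_scan", (DL_FUNC)&C_xtc_scan, 1},
    {"C_xtc_read_frame", (DL_FUNC)&C_xtc_read_frame, 2},
    {"C_xtc_write_frame", (DL_FUNC)&C_xtc_write_frame, 7},
    {"C_delaunay", (DL_FUNC)&C_delaunay, 2},
    {NULL, NULL, 0}};

void R_init_lipidvoro(DllInfo *dll) {
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
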