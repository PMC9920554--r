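/* Fused in-place Adam update.
 *
 * One pass over the parameter vector instead of ~10 allocating vector
 * operations in R; the L2 weight-decay term is folded into the gradient.
 * Bias correction is pre-folded by the caller:
 *   alpha = lr * sqrt(1 - beta2^t) / (1 - beta1^t)
 *   epsp  = eps * sqrt(1 - beta2^t)
 * The caller guarantees exclusive ownership of x, m and v.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

SEXP C_adam_update(SEXP x, SEXP g, SEXP m, SEXP v,
                   SEXP alpha, SEXP beta1, SEXP beta2, SEXP epsp, SEXP wd)
{
    R_xlen_t n = XLENGTH(x);
    double *xp = REAL(x), *gp = REAL(g), *mp = REAL(m), *vp = REAL(v);
    double a = asReal(alpha), b1 = asReal(beta1), b2 = asReal(beta2);
    double ep = asReal(epsp), w = asReal(wd);
    double ob1 = 1.0 - b1, ob2 = 1.0 - b2;

    for (R_xlen_t i = 0; i < n; i++) {
        double gi = gp[i] + w * xp[i];
        mp[i] = b1 * mp[i] + ob1 * gi;
        vp[i] = b2 * vp[i] + ob2 * gi * gi;
        xp[i] -= a * mp[i] / (sqrt(vp[i]) + ep);
    }
    return R_NilValue;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_adam_update", (DL_FUNC) &C_adam_update, 9},
    {NULL, NULL, 0}
};

void R_init_grapespec(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
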