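/* Right-hand side of the cyclin network ODE and a fixed-step RK4
 * integrator used on the sampler's hot path. Parameter layout
 * (n genes): [n, act[n], tinh[n], dinh[n], beta[n], alpha[n],
 * deltap[n], deltam, kappa, Ktx[n], htx[n], Kdeg[n], hdeg[n]];
 * state layout: [mRNA_1..mRNA_n, protein_1..protein_n]. */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

static void rhs_core(int n, const double *y, const double *p, double *dy)
{
    const double *act   = p + 1;
    const double *tinh  = p + 1 + n;
    const double *dinh  = p + 1 + 2 * n;
    const double *beta  = p + 1 + 3 * n;
    const double *alpha = p + 1 + 4 * n;
    const double *dp    = p + 1 + 5 * n;
    double deltam       = p[1 + 6 * n];
    double kappa        = p[2 + 6 * n];
    const double *Ktx   = p + 3 + 6 * n;
    const double *htx   = p + 3 + 7 * n;
    const double *Kdeg  = p + 3 + 8 * n;
    const double *hdeg  = p + 3 + 9 * n;

    for (int i = 0; i < n; i++) {
        double Pact = y[n + (int) act[i] - 1];
        double tx = beta[i] + alpha[i] * Pact;
        int ti = (int) tinh[i];
        if (ti > 0) {
            double c = y[n + ti - 1];
            if (c < 0) c = 0;
            tx /= 1.0 + pow(c / Ktx[i], htx[i]);
        }
        dy[i] = tx - deltam * y[i];

        double deg = dp[i] * y[n + i];
        int di = (int) dinh[i];
        if (di > 0) {
            double c = y[n + di - 1];
            if (c < 0) c = 0;
            deg /= 1.0 + pow(c / Kdeg[i], hdeg[i]);
        }
        dy[n + i] = kappa * y[i] - deg;
    }
}

SEXP C_cyclin_rhs(SEXP y_, SEXP parms_)
{
    const double *p = REAL(parms_);
    int n = (int) p[0];
    if (LENGTH(y_) != 2 * n)
        error("state length does not match model parameters");
    SEXP out = PROTECT(allocVector(REALSXP, 2 * n));
    rhs_core(n, REAL(y_), p, REAL(out));
    UNPROTECT(1);
    return out;
}

/* Classical RK4 with sub-stepping between requested output times.
 * hmax caps the internal step (chosen in R from the fastest rate so the
 * method stays accurate and stable). Concentrations are clamped at zero
 * after each step; divergence (any concentration above ymax, or
 * non-finite) aborts with success = FALSE. Returns
 * list(y = matrix[ntimes x 2n], success). */
SEXP C_integrate_rk4(SEXP y0_, SEXP times_, SEXP parms_, SEXP hmax_,
                     SEXP ymax_)
{
    const double *p = REAL(parms_);
    int n = (int) p[0];
    int ns = 2 * n;
    int nt = LENGTH(times_);
    const double *times = REAL(times_);
    double hmax = REAL(hmax_)[0];
    double ymax = REAL(ymax_)[0];
    if (LENGTH(y0_) != ns)
        error("state length does not match model parameters");

    SEXP ym = PROTECT(allocMatrix(REALSXP, nt, ns));
    double *Y = REAL(ym);
    double y[64], k1[64], k2[64], k3[64], k4[64], tmp[64];
    if (ns > 64) {
        UNPROTECT(1);
        error("model too large for compiled integrator (max 32 genes)");
    }
    for (int j = 0; j < ns; j++) y[j] = REAL(y0_)[j];
    int ok = 1;

    for (int j = 0; j < ns; j++) Y[0 * 1 + j * nt] = y[j];
    for (int i = 1; i < nt && ok; i++) {
        double dt = times[i] - times[i - 1];
        if (dt < 0) { ok = 0; break; }
        int nsub = dt > 0 ? (int) ceil(dt / hmax) : 0;
        double h = nsub > 0 ? dt / nsub : 0;
        for (int s = 0; s < nsub; s++) {
            rhs_core(n, y, p, k1);
            for (int j = 0; j < ns; j++) tmp[j] = y[j] + 0.5 * h * k1[j];
            rhs_core(n, tmp, p, k2);
            for (int j = 0; j < ns; j++) tmp[j] = y[j] + 0.5 * h * k2[j];
            rhs_core(n, tmp, p, k3);
            for (int j = 0; j < ns; j++) tmp[j] = y[j] + h * k3[j];
            rhs_core(n, tmp, p, k4);
            for (int j = 0; j < ns; j++) {
                y[j] += h / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
                if (y[j] < 0) y[j] = 0;
                if (!R_FINITE(y[j]) || y[j] > ymax) { ok = 0; }
            }
            if (!ok) break;
        }
        for (int j = 0; j < ns; j++) Y[i + j * nt] = ok ? y[j] : NA_REAL;
    }

    SEXP res = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(res, 0, ym);
    SET_VECTOR_ELT(res, 1, ScalarLogical(ok));
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("y"));
    SET_STRING_ELT(nms, 1, mkChar("success"));
    setAttrib(res, R_NamesSymbol, nms);
    UNPROTECT(3);
    return res;
}
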