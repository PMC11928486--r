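/* Compiled right-hand side and banded Jacobian of the benthic oxygen
   reaction-diffusion system, in deSolve's compiled-model convention.
   The R closures in R/benthic_o2.R define the same functions and remain
   the reference implementation used in tests; this path exists because
   the ODE machinery evaluates the rhs tens of thousands of times per
   diel solve.

   Parameter vector layout (doubles), packed by pack_o2_parms() in R:
     [0]       n (number of cells)
     [1]       k_o2
     [2]       csat
     [3]       cond_top
     [4]       lit flag (0/1)
     [5 .. 5+n-1]        cell widths w
     [5+n .. 5+2n-2]     face conductances cond (n-1 values)
     [5+2n-1 .. 5+3n-2]  lit production profile prod
     [5+3n-1 .. 5+4n-2]  saturated respiration profile rmax            */

#include <R.h>
#include <Rinternals.h>

#define MAX_O2_PARMS 8192
static double o2_parms[MAX_O2_PARMS];

void benthox_o2_init(void (*odeparms)(int *, double *))
{
    int n = MAX_O2_PARMS;
    odeparms(&n, o2_parms);
}

void benthox_o2_deriv(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const int n = (int) o2_parms[0];
    const double k = o2_parms[1];
    const double csat = o2_parms[2];
    const double cond_top = o2_parms[3];
    const int lit = o2_parms[4] > 0.5;
    const double *w = o2_parms + 5;
    const double *cond = o2_parms + 5 + n;
    const double *prod = o2_parms + 5 + 2 * n - 1;
    const double *rmax = o2_parms + 5 + 3 * n - 1;
    int i;
    /* flux entering cell i from above; f_below = flux leaving downward */
    double f_above = cond_top * (csat - y[0]);
    for (i = 0; i < n; i++) {
        double f_below = (i < n - 1) ? cond[i] * (y[i] - y[i + 1]) : 0.0;
        double ypos = y[i] > 0 ? y[i] : 0.0;
        double reac = (lit ? prod[i] : 0.0) - rmax[i] * ypos / (ypos + k);
        ydot[i] = (f_above - f_below) / w[i] + reac;
        f_above = f_below;
    }
}

void benthox_o2_jac(int *neq, double *t, double *y, int *ml, int *mu,
                    double *pd, int *nrowpd, double *yout, int *ip)
{
    const int n = (int) o2_parms[0];
    const double k = o2_parms[1];
    const double cond_top = o2_parms[3];
    const double *w = o2_parms + 5;
    const double *cond = o2_parms + 5 + n;
    const double *rmax = o2_parms + 5 + 3 * n - 1;
    const int nr = *nrowpd, m = *mu;
    int i, j;
    /* band storage: element (i, j) at pd[(i - j + mu) + j * nrowpd] */
    for (j = 0; j < n; j++) {
        double cu = (j == 0) ? cond_top : cond[j - 1];
        double cl = (j < n - 1) ? cond[j] : 0.0;
        double dresp = 0.0;
        if (y[j] > 0) {
            double denom = y[j] + k;
            dresp = rmax[j] * k / (denom * denom);
        }
        pd[(j - j + m) + j * nr] = -(cu + cl) / w[j] - dresp;
        if (j > 0)
            pd[((j - 1) - j + m) + j * nr] = cond[j - 1] / w[j - 1];
        if (j < n - 1)
            pd[((j + 1) - j + m) + j * nr] = cond[j] / w[j + 1];
    }
}
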