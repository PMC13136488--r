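/* Mass-action dynamics of a 3-node RNA binding circuit.
 *
 * State (9): x1 x2 x3 (free RNA copies), then complexes in canonical pair
 * order C11 C12 C13 C22 C23 C33.  Parameters (16): p1 p2 p3 (production,
 * copies/s, free species only), d (first-order degradation, 1/s, all
 * species), kf[6] and kr[6] per pair (per-copy association / dissociation).
 * Self-binding consumes two copies of the free species.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[16];
#define PROD(i)  parms[i]
#define DEG      parms[3]
#define KF(p)    parms[4 + (p)]
#define KR(p)    parms[10 + (p)]

/* canonical pair order [11, 12, 13, 22, 23, 33], zero-based node indices */
static const int PAIR_I[6] = {0, 0, 0, 1, 1, 2};
static const int PAIR_J[6] = {0, 1, 2, 1, 2, 2};

void circuit_initmod(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

void circuit_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int p, i, j;
    for (i = 0; i < 3; i++)
        ydot[i] = PROD(i) - DEG * y[i];
    for (p = 0; p < 6; p++) {
        double c = y[3 + p];
        double net;
        i = PAIR_I[p];
        j = PAIR_J[p];
        if (i == j) {
            net = KF(p) * y[i] * y[i] - KR(p) * c;
            ydot[i] -= 2.0 * net;
        } else {
            net = KF(p) * y[i] * y[j] - KR(p) * c;
            ydot[i] -= net;
            ydot[j] -= net;
        }
        ydot[3 + p] = net - DEG * c;
    }
}

static const R_CMethodDef cMethods[] = {
    {"circuit_initmod", (DL_FUNC) &circuit_initmod, 1},
    {"circuit_derivs",  (DL_FUNC) &circuit_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_rnacircgen(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
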