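/* Mass-action derivative of the four-step strand-separation mechanism
 *   E + S <-> FS <-> GSI <-> GSp <-> E + Sp
 * for use as a deSolve compiled model.  Species order in y:
 *   0 E, 1 S, 2 FS, 3 GSI, 4 GSp, 5 Sp   (concentrations in uM)
 * Parameter order: k1, k1r, k2, k2r, k3, k3r, k4, k4r
 * (k1, k4r in uM^-1 s^-1; the rest s^-1).
 */
#include <R.h>

static double parms[8];
#define K1F parms[0]
#define K1R parms[1]
#define K2F parms[2]
#define K2R parms[3]
#define K3F parms[4]
#define K3R parms[5]
#define K4F parms[6]
#define K4R parms[7]

void ccrm_initmod(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void ccrm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double E = y[0], S = y[1], FS = y[2], GSI = y[3], GSp = y[4], Sp = y[5];
    double bind = K1F * E * S;         /* association flux     */
    double rebind = K4R * E * Sp;      /* product rebinding    */

    ydot[1] = -bind + K1R * FS;                                   /* S   */
    ydot[2] = bind - (K1R + K2F) * FS + K2R * GSI;                /* FS  */
    ydot[3] = K2F * FS - (K2R + K3F) * GSI + K3R * GSp;           /* GSI */
    ydot[4] = K3F * GSI - (K3R + K4F) * GSp + rebind;             /* GSp */
    ydot[5] = K4F * GSp - rebind;                                 /* Sp  */
    ydot[0] = -bind + K1R * FS + K4F * GSp - rebind;              /* E   */
}
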