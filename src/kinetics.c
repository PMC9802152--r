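/* Compiled right-hand sides for the kinetic testbeds (deSolve interface).
 *
 * Rates span ~5 orders of magnitude, so ensembles need many stiff solves;
 * compiled derivatives keep least-squares refits tractable.
 */
#include <R.h>

/* ---- dual-phosphorylation mechanism -------------------------------------
 * state y = (E, S0, S1, S2, ES0, ES1)
 * parms  = (kf1, kr1, kcat1, kf2, kr2, kcat2)
 */
static double msp_parms[6];

void effparam_init_msp(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, msp_parms);
}

void effparam_deriv_msp(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double kf1 = msp_parms[0], kr1 = msp_parms[1], kc1 = msp_parms[2];
    double kf2 = msp_parms[3], kr2 = msp_parms[4], kc2 = msp_parms[5];
    double E = y[0], S0 = y[1], S1 = y[2], ES0 = y[4], ES1 = y[5];

    double v_bind1 = kf1 * E * S0;   /* E + S0 -> ES0 */
    double v_rel1  = kr1 * ES0;      /* ES0 -> E + S0 */
    double v_cat1  = kc1 * ES0;      /* ES0 -> ES1    */
    double v_bind2 = kf2 * E * S1;   /* E + S1 -> ES1 */
    double v_rel2  = kr2 * ES1;      /* ES1 -> E + S1 */
    double v_cat2  = kc2 * ES1;      /* ES1 -> E + S2 */

    ydot[0] = -v_bind1 + v_rel1 - v_bind2 + v_rel2 + v_cat2; /* E   */
    ydot[1] = -v_bind1 + v_rel1;                             /* S0  */
    ydot[2] = -v_bind2 + v_rel2;                             /* S1  */
    ydot[3] = v_cat2;                                        /* S2  */
    ydot[4] = v_bind1 - v_rel1 - v_cat1;                     /* ES0 */
    ydot[5] = v_cat1 + v_bind2 - v_rel2 - v_cat2;            /* ES1 */
}

/* ---- single-site caricature ---------------------------------------------
 * state y = (S0, E, S1, C);  parms = (kf, kr, kcat)
 */
static double car_parms[3];

void effparam_init_car(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, car_parms);
}

void effparam_deriv_car(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double kf = car_parms[0], kr = car_parms[1], kc = car_parms[2];
    double S0 = y[0], E = y[1], C = y[3];

    double v_bind = kf * E * S0;
    double v_rel  = kr * C;
    double v_cat  = kc * C;

    ydot[0] = -v_bind + v_rel;
    ydot[1] = -v_bind + v_rel + v_cat;
    ydot[2] = v_cat;
    ydot[3] = v_bind - v_rel - v_cat;
}
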