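/* Compiled right-hand side of the targeted radionuclide therapy model,
 * in the calling convention expected by deSolve's lsoda/lsodar.
 *
 * Units: time in days, volumes in ml, amounts in pmol, concentrations
 * in nM, cell counts in units of 1e7 cells.
 *
 * State vector (13 components):
 *   y[0]  a    active-antibody plasma concentration (nM)
 *   y[1]  b    inert-antibody plasma concentration (nM)
 *   y[2]  p    active-fragment plasma concentration (nM)
 *   y[3]  N    viable cancer cells (1e7)
 *   y[4]  D    damaged cancer cells (1e7)
 *   y[5]  fFN  free receptor fraction on viable cells
 *   y[6]  fAN  active receptor fraction on viable cells
 *   y[7]  uFD  D * fFD, free-receptor cell-equivalents on damaged cells
 *   y[8]  uAD  D * fAD, active-receptor cell-equivalents on damaged cells
 *   y[9]  Abl  cumulative decays of plasma-resident nuclides (pmol)
 *   y[10] cumV cumulative decays on viable-cell receptors (pmol)
 *   y[11] cumD cumulative decays on damaged-cell receptors (pmol)
 *   y[12] born cumulative newborn viable cells (1e7)
 *
 * The damaged-cell receptor fractions are integrated as the absolute
 * amounts uFD = D*fFD and uAD = D*fAD, which removes the N/D
 * singularity of the fraction equations at D -> 0 exactly:
 *   uFD' = RD*N*fFN - (kon*(a+b) + omega)*uFD
 *   uAD' = RD*N*fAN + kon*a*uFD - (lambda + omega)*uAD
 */

#include <R.h>

static double parms[16];
#define lam    parms[0]   /* radionuclide decay rate, 1/day            */
#define kon    parms[1]   /* binding rate, 1/(nM day)                  */
#define kapc   parms[2]   /* intact-antibody clearance rate, 1/day     */
#define kapp   parms[3]   /* fragment clearance rate, 1/day            */
#define gam    parms[4]   /* receptors per 1e7 cells, pmol             */
#define vol    parms[5]   /* volume of distribution, ml                */
#define nu     parms[6]   /* lesion volume per 1e7 cells, ml           */
#define ks     parms[7]   /* relative significance of self-damage      */
#define rho    parms[8]   /* proliferation rate, 1/day                 */
#define omg    parms[9]   /* damaged-cell death rate, 1/day            */
#define alph   parms[10]  /* radiosensitivity                          */
#define kfree  parms[11]  /* weight of unanchored-nuclide decays       */
#define cdth   parms[12]  /* lethal burden, 1e7 cells (root function)  */
#define ablcr  parms[13]  /* lethal blood decays, pmol (root function) */
#define droot  parms[14]  /* 1: lethal-burden crossing is terminal      */
#define txroot parms[15]  /* 1: toxicity crossing is terminal           */

void trt_initmod(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

/* Solver excursions below 0 (noise at the absolute-tolerance floor
 * once a population is extinct) must not feed back into the dynamics:
 * every state component is clamped to >= 0 where it enters a term. */
#define POS(z) ((z) > 0.0 ? (z) : 0.0)

void trt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double a = POS(y[0]), b = POS(y[1]), p = POS(y[2]);
    double N = POS(y[3]), D = POS(y[4]);
    double fFN = POS(y[5]), fAN = POS(y[6]);
    double uFD = POS(y[7]), uAD = POS(y[8]);
    double M = N + D;
    /* cross-fire term is defined as 0 for an empty lesion */
    double cross = (M > 1e-30) ? lam * gam * (fAN * N + uAD) / (nu * M) : 0.0;
    double RD = alph * (ks * lam * gam * fAN / nu + (1.0 - ks) * cross
                        + kfree * lam * (a + p));
    double bfree = fFN * N + uFD;   /* free-receptor cell-equivalents */

    ydot[0]  = -lam * a - kon * a * gam / vol * bfree - kapc * a;
    ydot[1]  =  lam * a - kon * b * gam / vol * bfree - kapc * b;
    ydot[2]  =  omg * gam * uAD / vol - lam * p - kapp * p;
    ydot[3]  =  rho * N - RD * N;
    ydot[4]  =  RD * N - omg * D;
    ydot[5]  = (1.0 - fFN) * rho - kon * (a + b) * fFN;
    ydot[6]  =  kon * a * fFN - (lam + rho) * fAN;
    ydot[7]  =  RD * N * fFN - (kon * (a + b) + omg) * uFD;
    ydot[8]  =  RD * N * fAN + kon * a * uFD - (lam + omg) * uAD;
    ydot[9]  =  lam * (a + p) * vol;
    ydot[10] =  lam * gam * fAN * N;
    ydot[11] =  lam * gam * uAD;
    ydot[12] =  rho * N;
}

/* Terminal endpoints: lethal cancer burden N + D = Cd and lethal
 * cumulative blood decays Abl = Ablcr. */
void trt_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    gout[0] = (droot  > 0.5) ? y[3] + y[4] - cdth : -1.0;
    gout[1] = (txroot > 0.5) ? y[9] - ablcr : -1.0;
}
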