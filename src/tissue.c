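/* Compiled right-hand sides for the tissue stage, in the deSolve compiled-
 * model convention (initfunc / initforc / derivs looked up by name in this
 * package's DLL).
 *
 * derivs_muscle integrates n independent 2-state lineage blocks (S_i, M_i)
 * that share the muscle parameters and the exposure forcing y(t) but each
 * carry their own threshold Rd_i.  Fitting exploits this to sweep a whole
 * Rd grid in a single solver call; plain simulation uses n = 1.  The state
 * layout is (S_1, M_1, S_2, M_2, ...), so the Jacobian is block-diagonal
 * with 2x2 blocks and a banded (1,1) structure.
 *
 * The parameter vector has the fixed length 7 + MAXRD (deSolve requires the
 * length passed from R to match); slot 6 holds the number of blocks in use.
 */

#include <R.h>
#include <math.h>

#define MAXRD 512

static double mus_p[7 + MAXRD]; /* p0 p1 nu0 nu1 d0 m n Rd[0..MAXRD-1] */
static double mus_f[1];         /* forcing: y(t) */

void initmod_muscle(void (*odeparms)(int *, double *))
{
    int N = 7 + MAXRD;
    odeparms(&N, mus_p);
}

void initforc_muscle(void (*odeforcs)(int *, double *))
{
    int N = 1;
    odeforcs(&N, mus_f);
}

void derivs_muscle(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double p0 = mus_p[0], p1 = mus_p[1], nu0 = mus_p[2],
                 nu1 = mus_p[3], d0 = mus_p[4], m = mus_p[5];
    const int n = (int) mus_p[6];
    const double yexp = mus_f[0];

    for (int i = 0; i < n; i++) {
        const double S = y[2 * i], M = y[2 * i + 1];
        const double Rd = mus_p[7 + i];
        const double fb = 1.0 / (1.0 + M / m);
        const double p = p0 + p1 * fb;
        const double nu = nu0 + nu1 * fb;
        const double r = yexp / Rd;
        const double f = 1.0 - r * r * r;
        const double flux = f * nu * S;
        ydot[2 * i]     = (2.0 * p - 1.0) * flux;
        ydot[2 * i + 1] = 2.0 * (1.0 - p) * flux - d0 * M;
    }
}

/* Paired lineage system for finite-difference sensitivity: one nominal and
 * one perturbed 2-state block, each with its own full muscle parameter set,
 * threshold and exposure forcing, integrated jointly so that both share the
 * solver's step sequence.  Truncation errors of the two blocks are then
 * highly correlated and cancel in the lean-mass difference, which is the
 * quantity the sensitivity quotient divides by an epsilon-level number. */

static double pair_p[14];  /* (p0 p1 nu0 nu1 d0 m Rd) x 2 */
static double pair_f[2];   /* forcings: y_nominal(t), y_perturbed(t) */

void initmod_muscle_pair(void (*odeparms)(int *, double *))
{
    int N = 14;
    odeparms(&N, pair_p);
}

void initforc_muscle_pair(void (*odeforcs)(int *, double *))
{
    int N = 2;
    odeforcs(&N, pair_f);
}

void derivs_muscle_pair(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    for (int i = 0; i < 2; i++) {
        const double *q = pair_p + 7 * i;
        const double S = y[2 * i], M = y[2 * i + 1];
        const double fb = 1.0 / (1.0 + M / q[5]);
        const double p = q[0] + q[1] * fb;
        const double nu = q[2] + q[3] * fb;
        const double r = pair_f[i] / q[6];
        const double f = 1.0 - r * r * r;
        const double flux = f * nu * S;
        ydot[2 * i]     = (2.0 * p - 1.0) * flux;
        ydot[2 * i + 1] = 2.0 * (1.0 - p) * flux - q[4] * M;
    }
}

/* Exponential-linear tumour with concentration-proportional kill, driven by
 * the tissue concentration forcing C2(t).  Kept in a separate system from
 * the lineage blocks: the two share no state, and a joint adaptive solve
 * would let tumour parameters perturb the muscle output through step-size
 * selection. */

static double tum_p[4];  /* mu0 mu1 eta kappa */
static double tum_f[1];  /* forcing: C2(t) */

void initmod_tumour(void (*odeparms)(int *, double *))
{
    int N = 4;
    odeparms(&N, tum_p);
}

void initforc_tumour(void (*odeforcs)(int *, double *))
{
    int N = 1;
    odeforcs(&N, tum_f);
}

void derivs_tumour(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double mu0 = tum_p[0], mu1 = tum_p[1], eta = tum_p[2],
                 kappa = tum_p[3];
    const double T = y[0];
    const double g = mu0 * T / mu1;
    ydot[0] = mu0 * T * pow(1.0 + pow(g, eta), -1.0 / eta)
            - kappa * tum_f[0] * T;
}
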