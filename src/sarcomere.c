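/* Compiled right-hand side of the mean-field sarcomere model, in the form
 * expected by deSolve's compiled-model interface.
 *
 * States: y[0] = G_XB (fraction of formed cross-bridge groups)
 *         y[1] = A    (fraction of TnC with bound calcium)
 *         y[2] = s    (mean cross-bridge strain, dimensionless)
 *
 * In unloaded mode the stretch ratio lambda is not a state: contraction is
 * quasi-static against the cell's own stiffness, so lambda is slaved to the
 * instantaneous magnitude balance |T_p(lambda)| = T_a, which for the
 * exponential passive law has the closed form
 *   lambda = 1 - log(1 + T_a / passive_alpha) / passive_beta.
 * d lambda/dt is then obtained by the chain rule and substituted into the
 * strain equation ds/dt = kappa_s * dlambda/dt - s/tau_s, giving a linear
 * equation in ds/dt that is solved exactly (see the R-level documentation).
 */

#include <R.h>
#include <math.h>

#define N_PARMS 22

static double p[N_PARMS];

#define CA_AMP    p[0]
#define CA_DIAST  p[1]
#define TAU2      p[2]
#define N_A       p[3]
#define A_50      p[4]
#define P_ALPHA   p[5]
#define P_BETA    p[6]
#define S_A       p[7]
#define TAU1      p[8]
#define T_START   p[9]
#define K_F       p[10]
#define N_G       p[11]
#define K_G       p[12]
#define C_S       p[13]
#define TAU_S     p[14]
#define K_ON      p[15]
#define K_OFF     p[16]
#define KAPPA_S   p[17]
#define MODE      p[18]   /* 0 = unloaded quasi-static, 1 = fixed lambda */
#define LAM_FIX   p[19]
#define CA_MODE   p[20]   /* 0 = biexponential transient, 1 = clamped constant */
#define CA_CONST  p[21]

void sarco_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

/* Biexponential calcium transient; beta is the exact extremum of
 * exp(-u/tau1) - exp(-u/tau2) so the peak equals Ca_amp. */
static double ca_drive(double t)
{
    double r, beta, u;
    if (CA_MODE > 0.5)
        return CA_CONST;
    if (t <= T_START)
        return CA_DIAST;
    r = TAU1 / TAU2;
    beta = pow(r, -1.0 / (r - 1.0)) - pow(r, -r / (r - 1.0));
    u = t - T_START;
    return CA_DIAST + (CA_AMP - CA_DIAST) / beta * (exp(-u / TAU1) - exp(-u / TAU2));
}

void sarco_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double G = y[0], A = y[1], s = y[2];
    double Ca, dA, Apos, An, Abar, fG, gG, dG, phi, phip, Ta, lam, dlam, ds;

    Ca = ca_drive(*t);
    dA = K_ON * Ca * (1.0 - A) - K_OFF * A;

    Apos = (A > 0.0) ? A : 0.0;
    An = pow(Apos, N_A);
    Abar = An / (An + pow(A_50, N_A));
    fG = K_F * pow(Abar, N_G);
    gG = K_G * (1.0 + C_S * s * s);
    dG = fG * (1.0 - G) - gG * G;

    phi = (1.0 + s > 0.0) ? (1.0 + s) : 0.0;
    phip = (1.0 + s > 0.0) ? 1.0 : 0.0;
    Ta = S_A * G * phi;

    if (MODE > 0.5) {
        lam = LAM_FIX;
        dlam = 0.0;
        ds = -s / TAU_S;
    } else {
        double c, denom;
        lam = 1.0 - log1p(Ta / P_ALPHA) / P_BETA;
        c = S_A / (P_BETA * (P_ALPHA + Ta));
        denom = 1.0 + KAPPA_S * c * G * phip;
        ds = (-KAPPA_S * c * phi * dG - s / TAU_S) / denom;
        dlam = -c * (dG * phi + G * phip * ds);
    }

    ydot[0] = dG;
    ydot[1] = dA;
    ydot[2] = ds;

    if (*ip > 0) {
        double Tp = (lam < 1.0)
            ? P_ALPHA * (1.0 - exp(P_BETA * (1.0 - lam)))
            : P_ALPHA * (exp(P_BETA * (lam - 1.0)) - 1.0);
        yout[0] = lam;
        yout[1] = Ca;
        yout[2] = Ta;
        yout[3] = Tp;
    }
}
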