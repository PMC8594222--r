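/* Simplified six-equation tumor-immune system model, compiled right-hand
 * side for deSolve.  State: C, N, T, M, H, R, A (A = cumulative anti-CD25
 * exposure, dA/dt = u_a * C).  The treatment signals are piecewise constant;
 * the integrator is restarted at every window boundary, so the signal values
 * for the current segment are passed in as the last three parameters.
 */
#include <R.h>
#include <math.h>

#define NPAR 60
static double p[NPAR];

/* order matches .tis_param_names in R/parameters.R, then u5, ua, sgn */
#define a1    p[0]
#define Cmax  p[1]
#define b1    p[2]
#define c1    p[3]
#define d1    p[4]
#define e1    p[5]
#define f1    p[6]
#define g1    p[7]
#define h1    p[8]
#define k1    p[9]
#define l1    p[10]
#define a2    p[11]
#define b2    p[12]
#define c2    p[13]
#define d2    p[14]
#define e2    p[15]
#define f2    p[16]
#define g2    p[17]
#define h2    p[18]
#define a3    p[19]
#define b3    p[20]
#define c3    p[21]
#define d3    p[22]
#define e3    p[23]
#define f3    p[24]
#define g3    p[25]
#define h3    p[26]
#define k3    p[27]
#define l3    p[28]
#define m3    p[29]
#define n3    p[30]
#define p3    p[31]
#define a4    p[32]
#define b4n   p[33]
#define b4f   p[34]
#define c4    p[35]
#define d4    p[36]
#define a5    p[37]
#define b5    p[38]
#define c5    p[39]
#define d5    p[40]
#define e5    p[41]
#define f5    p[42]
#define g5    p[43]
#define a6    p[44]
#define b6    p[45]
#define c6    p[46]
#define d6    p[47]
#define e6    p[48]
#define f6    p[49]
#define g6    p[50]
#define h6    p[51]
#define rIa   p[52]  /* tau1/alpha1 */
#define rb1   p[53]  /* beta1/tau2  */
#define rb2   p[54]  /* beta2/tau2  */
#define rb3   p[55]  /* beta3/tau2  */
#define rLS   p[56]  /* lambda1/tau3 */
#define u5    p[57]  /* 5-FU signal on current segment */
#define ua    p[58]  /* anti-CD25 signal on current segment */
#define sgn   p[59]  /* arm-level anti-CD25 indicator */

void tis_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void tis_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double C = y[0] > 0 ? y[0] : 0;
    double N = y[1] > 0 ? y[1] : 0;
    double T = y[2] > 0 ? y[2] : 0;
    double M = y[3] > 0 ? y[3] : 0;
    double H = y[4] > 0 ? y[4] : 0;
    double R = y[5] > 0 ? y[5] : 0;
    double A = y[6] > 0 ? y[6] : 0;

    double Cl  = C > 1 ? C : 1;           /* floor inside the Gompertz log */
    double acc = C / (1 + cbrt(C) / l1);  /* accessible surface layer */
    double Fcy = rb1 * T + rb2 * N + rb3 * H;      /* QSS IFN-gamma */
    double treg = (1 + e1 * R) / (1 + d1 * ua * ua * R * R * R);
    double dM3  = M - p3;

    double dC = a1 * C * log(Cmax / Cl)
        - b1 * N * acc
        - (c1 * T * acc) / (treg * (1 + f1 * rLS * C))
        - (u5 > 0 ? g1 * C : 0)
        - h1 * log1p(k1 * sgn * A) * C / (C + 1);
    /* the anti-CD25 log-kill is capacity-limited by the cells available
     * (factor C/(C+1), negligible above ~100 cells), so C = 0 is a smooth
     * absorbing state */
    if (y[0] <= 0 && dC < 0) dC = 0;

    double dN = a2 - b2 * N
        + c2 * H * N / (d2 * rIa + H)
        + e2 * Fcy * N / (f2 + Fcy)
        - g2 * N * acc
        - h2 * R * N;

    double dT = -a3 * T
        + b3 * T * C * C / (c3 + C * C)
        + d3 * N * acc * ((1 - m3) / (1 + n3 * dM3 * dM3) + m3)
        - e3 * T * acc
        + f3 * H * T / (g3 * rIa + H)
        + h3 * Fcy * T / (k3 + Fcy)
        - l3 * R * T;

    double dMd = a4 - (u5 > 0 ? b4f : b4n) * M + c4 * C / (d4 + C);

    double dH = a5 - b5 * H
        + c5 * H * H / (d5 * rIa + H)
        + e5 * Fcy * H / (f5 + Fcy)
        - g5 * R * H;

    double dR = a6 - b6 * R + c6 * T + d6 * H
        + e6 * H * R / (f6 * rIa + H)
        - g6 * N * R
        - h6 * ua * R;

    ydot[0] = dC;
    ydot[1] = dN;
    ydot[2] = dT;
    ydot[3] = dMd;
    ydot[4] = dH;
    ydot[5] = dR;
    ydot[6] = ua * C;
}
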