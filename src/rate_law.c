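/* Compiled rate law for deSolve: binary-choice smoking dynamics with a
 * time-varying individual utility. The knowledge proxy n(t) enters as a
 * linearly interpolated forcing series. */
#include <R.h>
#include <math.h>

static double parms[8];
static double forc[1];
#define a_par      parms[0]
#define b_par      parms[1]
#define form_par   parms[2]   /* 1 discounted, 2 step, 3 constant */
#define u0_par     parms[3]
#define uinf_par   parms[4]
#define logd_par   parms[5]   /* log(delta); -700 stands in for delta = 0 */
#define tstar_par  parms[6]
#define uconst_par parms[7]
#define n_t forc[0]

void sd_initmod(void (*odeparms)(int *, double *)) {
  int N = 8;
  odeparms(&N, parms);
}

void sd_initforc(void (*odeforcs)(int *, double *)) {
  int N = 1;
  odeforcs(&N, forc);
}

void sd_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip) {
  double x = y[0];
  if (x < 0.0) x = 0.0;        /* guard solver trial states; pow(0, a<1)   */
  if (x > 1.0) x = 1.0;        /* takes the continuous extension 0         */
  double u;
  if (form_par < 1.5) {
    u = uinf_par + exp(n_t * logd_par) * (u0_par - uinf_par);
  } else if (form_par < 2.5) {
    u = (*t < tstar_par) ? u0_par : uinf_par;
  } else {
    u = uconst_par;
  }
  ydot[0] = b_par * ((1.0 - x) * pow(x, a_par) * u
                     - x * pow(1.0 - x, a_par) * (1.0 - u));
}
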