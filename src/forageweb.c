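/* Compiled right-hand side of the food-web delay-differential system,
 * in the deSolve compiled-model convention (initmod/derivs + lagvalue
 * via R_GetCCallable). Mirrors the R-level right-hand side in
 * R/simulate.R exactly; the parameter packing is defined in
 * R/simulate_c.R and must stay in step with the offsets below.
 *
 * Policy kinds (per fished species): 0 closed, 1 open access,
 * 2 open-loop piecewise-linear effort knots, 3 constant fishing
 * mortality, 4 sardine harvest-guideline feedback, 5 sardine
 * hockey-stick feedback, 6 myopic profit-maximizing feedback.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define MAXK 80
#define NPARMS 565

/* offsets into the packed parameter vector */
#define IP_SETTINGS   0   /* kappa_in_numbers_loss, lagged_rep_prey */
#define IP_ANCH       2   /* r_bar, A, p, s, w_r, w_inf, kappa, M   */
#define IP_SARD      10
#define IP_HAL       18   /* a, b, M_j, tau, kappa, w_r, w_inf0,
                             Cmax, alpha_a, alpha_s, Y, gamma_w, M,
                             f_base */
#define IP_PEL       32   /* Mbar, tau_bp, Phi, K_bp, z, thr1..3,
                             ths1..3, Gamma_a, Gamma_s, Gamma_other,
                             Xa_o, Xs_o, phi_floor */
#define IP_ECON      49   /* 3 x (p_tilde, q, c1, c2)               */
#define IP_POLC      61   /* hcr_cutoff, hcr_cap, hcr_share, hcr_f0,
                             hcr_f1, hs_lower, hs_upper, hs_fmax    */
#define IP_Y0        69   /* 7 initial states (constant history)    */
#define IP_KIND      76   /* 3 policy kinds                         */
#define IP_PCONST    79   /* 3 policy constants (constant_F value)  */
#define IP_NK        82   /* 3 knot counts                          */
#define IP_KNOTS     85   /* 3 x (MAXK knots, MAXK values)          */

static double parms[NPARMS];

static void (*lagvalue_fn)(double, int *, int, double *) = NULL;

void fw_initmod(void (*odeparms)(int *, double *))
{
    int N = NPARMS;
    odeparms(&N, parms);
    lagvalue_fn = (void (*)(double, int *, int, double *))
        R_GetCCallable("deSolve", "lagvalue");
}

static double recr_rate(double t, const double *fp)
{
    /* fp: r_bar, A, p, s, ... */
    if (fp[1] == 0.0) return fp[0];
    return fp[0] * exp(fp[1] * sin(2.0 * M_PI * t / fp[2] +
                                   fp[3] * M_PI / 180.0 + M_PI) -
                       fp[1] * fp[1] / 4.0);
}

/* saturating prey-response scalar, x = d - theta1 */
static double phi_scalar(double x, double c0, double c3)
{
    double num, den;
    if (x <= 0.0) return 0.0;
    num = c3 * x;
    den = c0 + num;
    if (den <= 0.0) return 0.0;
    return (num >= den) ? 1.0 : num / den;
}

static double interp_knots(double t, const double *kn, const double *vv,
                           int n)
{
    int lo, hi, mid;
    double w;
    if (n < 1) return 0.0;
    if (t <= kn[0]) return vv[0];
    if (t >= kn[n - 1]) return vv[n - 1];
    lo = 0; hi = n - 1;
    while (hi - lo > 1) {
        mid = (lo + hi) / 2;
        if (kn[mid] <= t) lo = mid; else hi = mid;
    }
    w = (t - kn[lo]) / (kn[hi] - kn[lo]);
    return (1.0 - w) * vv[lo] + w * vv[hi];
}

static double effort(int i, double t, const double *y)
{
    int kind = (int) parms[IP_KIND + i];
    const double *ec = parms + IP_ECON + 4 * i;
    double X = y[2 * i];           /* Xa, Xs, Xh */
    double E = 0.0;

    if (X < 0.0) X = 0.0;
    switch (kind) {
    case 0:                        /* closed */
        E = 0.0;
        break;
    case 1:                        /* open access: zero average profit */
        E = (ec[0] * ec[1] * X - ec[2]) / ec[3];
        break;
    case 2:                        /* open-loop knots */
        E = interp_knots(t, parms + IP_KNOTS + i * 2 * MAXK,
                         parms + IP_KNOTS + i * 2 * MAXK + MAXK,
                         (int) parms[IP_NK + i]);
        break;
    case 3:                        /* constant F */
        E = parms[IP_PCONST + i] / ec[1];
        break;
    case 4: {                      /* sardine harvest guideline */
        const double *pc = parms + IP_POLC;
        const double *sp = parms + IP_SARD;
        double rs = recr_rate(t, sp);
        double Fs = pc[3] + pc[4] * rs / sp[0];
        double C;
        if (X <= pc[0]) C = 0.0;
        else {
            C = pc[2] * (X - pc[0]) * Fs;
            if (C > pc[1]) C = pc[1];
        }
        E = (X > 0.0) ? C / (X * ec[1]) : 0.0;
        break;
    }
    case 5: {                      /* sardine hockey stick */
        const double *pc = parms + IP_POLC;
        double Xso = parms[IP_PEL + 15];
        double Ms = parms[IP_SARD + 7];
        double x = X / Xso;
        double Fmax = pc[7] * Ms;
        double F;
        if (x <= pc[5]) F = 0.0;
        else if (x >= pc[6]) F = Fmax;
        else F = Fmax / (pc[6] - pc[5]) * (x - pc[5]);
        E = F / ec[1];
        break;
    }
    case 6:                        /* myopic static optimum */
        E = (ec[0] * ec[1] * X - ec[2]) / (2.0 * ec[3]);
        break;
    default:
        E = 0.0;
    }
    return (E > 0.0) ? E : 0.0;
}

void fw_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double *ap = parms + IP_ANCH;
    const double *sp = parms + IP_SARD;
    const double *hp = parms + IP_HAL;
    const double *pp = parms + IP_PEL;
    const double *y0 = parms + IP_Y0;
    double yc[7];
    int j;

    for (j = 0; j < 7; j++) yc[j] = (y[j] > 0.0) ? y[j] : 0.0;
    double Xa = yc[0], Na = yc[1], Xs = yc[2], Ns = yc[3];
    double Xh = yc[4], Nh = yc[5], Nbp = yc[6];

    double Ea = effort(0, *t, yc), Es = effort(1, *t, yc),
           Eh = effort(2, *t, yc);
    double Fa = parms[IP_ECON + 1] * Ea;
    double Fs = parms[IP_ECON + 5] * Es;
    double Fh = parms[IP_ECON + 9] * Eh;

    double ra = recr_rate(*t, ap), rs = recr_rate(*t, sp);

    /* Type-II multi-prey predation and consumption-dependent growth */
    double avail = hp[8] * Xa + hp[9] * Xs + hp[10];
    double D = hp[7] + avail;
    double Pa = hp[7] * hp[8] * Xh / D;
    double Ps = hp[7] * hp[9] * Xh / D;
    double w_inf_h = hp[6] * pow((avail / D) / hp[13], hp[11]);

    double la = ap[7] + Pa + Fa, ls = sp[7] + Ps + Fs;
    ydot[0] = ra * ap[4] * Na + ap[6] * (ap[5] * Na - Xa) - la * Xa;
    ydot[1] = (ra - la) * Na;
    ydot[2] = rs * sp[4] * Ns + sp[6] * (sp[5] * Ns - Xs) - ls * Xs;
    ydot[3] = (rs - ls) * Ns;

    /* halibut delayed Beverton-Holt recruitment */
    double tau_h = hp[3], Xh_lag;
    if (tau_h <= 0.0) Xh_lag = Xh;
    else if (*t - tau_h <= 0.0) Xh_lag = y0[4];
    else {
        int nr = 4;                 /* 0-based state index */
        double yl;
        lagvalue_fn(*t - tau_h, &nr, 1, &yl);
        Xh_lag = (yl > 0.0) ? yl : 0.0;
    }
    double Rh = hp[0] * exp(-hp[2] * tau_h) * Xh_lag /
        (1.0 + hp[1] * Xh_lag);
    double kN = (parms[IP_SETTINGS] != 0.0) ? hp[4] : 0.0;
    ydot[4] = Rh * hp[5] + hp[4] * (w_inf_h * Nh - Xh) -
        (hp[12] + Fh) * Xh;
    ydot[5] = Rh - (hp[12] + Fh + kN) * Nh;

    /* Pelican: lagged reproduction, current-prey mortality */
    double tau_bp = pp[1], Xa_l, Xs_l, Nbp_l;
    if (tau_bp <= 0.0) {
        Xa_l = Xa; Xs_l = Xs; Nbp_l = Nbp;
    } else if (*t - tau_bp <= 0.0) {
        Xa_l = y0[0]; Xs_l = y0[2]; Nbp_l = y0[6];
    } else {
        int nr[3] = {0, 2, 6};
        double yl[3];
        lagvalue_fn(*t - tau_bp, nr, 3, yl);
        Xa_l = (yl[0] > 0.0) ? yl[0] : 0.0;
        Xs_l = (yl[1] > 0.0) ? yl[1] : 0.0;
        Nbp_l = (yl[2] > 0.0) ? yl[2] : 0.0;
    }
    double d_now = pp[11] * Xa / pp[14] + pp[12] * Xs / pp[15] + pp[13];
    double d_rep = (parms[IP_SETTINGS + 1] != 0.0) ?
        (pp[11] * Xa_l / pp[14] + pp[12] * Xs_l / pp[15] + pp[13]) : d_now;

    double r_c3 = pp[7] * (1.0 - pp[5] - pp[6]);
    double r_c0 = (1.0 - pp[5]) * pp[6] * (1.0 - pp[7]);
    double s_c3 = pp[10] * (1.0 - pp[8] - pp[9]);
    double s_c0 = (1.0 - pp[8]) * pp[9] * (1.0 - pp[10]);
    double phi_r = phi_scalar(d_rep - pp[5], r_c0, r_c3);
    double phi_v = phi_scalar(d_now - pp[8], s_c0, s_c3);
    if (phi_v < pp[16]) phi_v = pp[16];

    double dens = 1.0 + (pp[2] - 1.0) *
        (1.0 - pow(Nbp_l / pp[3], pp[4]));
    if (dens < 0.0) dens = 0.0;
    double beta_bp = 0.5 * exp(-pp[0] * tau_bp);
    ydot[6] = beta_bp * Nbp_l * phi_r * dens -
        (pp[0] - log(phi_v)) * Nbp;
}
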