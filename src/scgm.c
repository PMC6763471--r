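/* Right-hand sides for the single-cell growth model (SCGM) and the coupled
 * mother-bud variant, in the deSolve compiled-code calling convention.
 *
 * Internal unit system: length um, time s, pressure Pa, amount mmol,
 * concentration mmol um^-3 (1 mM = 1e-15 mmol um^-3).  RT is pre-multiplied
 * on the R side so that Pi = c * RT_int is in Pa.
 */
#include <R.h>
#include <math.h>

#define FOUR_PI 12.566370614359172

/* ---------------- single compartment (with HOG extension states) -------- */

/* parms: 0 L_p, 1 E, 2 nu, 3 d, 4 phi, 5 Pi_ct, 6 k_u, 7 k_c, 8 c_e,
 *        9 V_b, 10 RT, 11 k_act, 12 k_deact, 13 k_gly, 14 k_leak, 15 Pi_ref
 * state: 0 V_os, 1 Pi_t, 2 c_i, 3 ln_rref, 4 H, 5 c_gly
 * yout:  0 J_w
 */
static double sp[16];

void scgm_init(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, sp);
}

void scgm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double L_p = sp[0], E = sp[1], nu = sp[2], d = sp[3], phi = sp[4],
                 Pi_ct = sp[5], k_u = sp[6], k_c = sp[7], c_e = sp[8],
                 V_b = sp[9], RT = sp[10], k_act = sp[11], k_deact = sp[12],
                 k_gly = sp[13], k_leak = sp[14], Pi_ref = sp[15];

    const double V_os = y[0], Pi_t = y[1], c_i = y[2], H = y[4],
                 c_gly = y[5];

    const double V_t = V_os + V_b;
    const double r = cbrt(3.0 * V_t / FOUR_PI);
    const double G = FOUR_PI * r * r;

    const double Pi_i = (c_i + c_gly) * RT;
    const double Pi_e = c_e * RT;

    const double J_w = L_p * G * (Pi_t + Pi_e - Pi_i); /* >0 outward */
    const double dV_os = -J_w;
    const double rdot = dV_os / G; /* V_b constant */

    /* osmolyte balance: uptake over the surface, consumption with total
     * cell volume, dilution by the osmotic water */
    const double dc_i = (k_u * G - k_c * V_t) / V_os - c_i * dV_os / V_os;

    const double fm = (Pi_t >= Pi_ct) ? (Pi_t - Pi_ct) : 0.0;
    double dPi = 2.0 * E * d / (1.0 - nu) * rdot / (r * r)
                 - Pi_t * rdot / r
                 - E * phi / (1.0 - nu) * fm;
    /* no negative turgor: wall cannot be pulled inward by the membrane */
    if (Pi_t <= 0.0 && dPi < 0.0) dPi = 0.0;

    const double dlnrref = phi * r / (2.0 * d) * fm;

    const double deficit = (Pi_t < Pi_ref) ? (1.0 - Pi_t / Pi_ref) : 0.0;
    const double dH = k_act * deficit * (1.0 - H) - k_deact * H;
    const double dc_gly = k_gly * H - k_leak * c_gly - c_gly * dV_os / V_os;

    ydot[0] = dV_os;
    ydot[1] = dPi;
    ydot[2] = dc_i;
    ydot[3] = dlnrref;
    ydot[4] = dH;
    ydot[5] = dc_gly;

    if (ip[0] > 0) yout[0] = J_w;
}

/* ------- coupled mother + buds, fast-exchange (shared cytoplasm) limit --
 *
 * In the limit of fast inter-compartment exchange the compartments share
 * one osmolarity c and one turgor Pi.  Each wall obeys the integrated
 * elasto-viscoplastic relation  ln r_j = ln rref_j + a_j Pi r_j  with
 * a_j = (1-nu)/(2 d E_j).  The shared turgor evolves by differentiating
 * the water constraint  sum_j V(r_j) = V_tot_os + sum_j V_b_j :
 *
 *   dPi/dt = (dV_tot/dt - sum_j B_j dlnrref_j/dt) / sum_j A_j,
 *   A_j = 4 pi a_j r_j^4 / (1 - a_j Pi r_j),
 *   B_j = 4 pi r_j^3 / (1 - a_j Pi r_j),
 *
 * which for a single compartment reduces exactly to the turgor ODE of
 * the single-cell model.  Slow states: total osmotic volume, total
 * osmolyte amount, shared turgor, per-compartment ln rref.
 *
 * parms: same layout as the explicit coupled model (L_x, k_x unused).
 * state: 0 V_tot_os, 1 N, 2 Pi, 3.. ln rref_j (mother first)
 * yout:  0.. r_j
 */
static double fp[20];
static double warm_r[3];
static int warm_ok;

void cscgm_fast_init(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, fp);
    warm_ok = 0;
}

/* solve ln r - aP r = lnrref on the stable branch (1 - aP r > 0) */
static double wall_radius(double lnrref, double aP, double r0)
{
    double rref = exp(lnrref), lo, hi, r, g, gp;
    int it;
    if (aP > 0.0) {
        if (-log(aP) - 1.0 - lnrref < 0.0)
            return -1.0; /* no equilibrium: elastic runaway */
        lo = rref;
        hi = 1.0 / aP;
    } else {
        lo = 1e-8 * rref;
        hi = rref;
    }
    r = (r0 > lo && r0 < hi) ? r0 : 0.5 * (lo + hi);
    for (it = 0; it < 200; it++) {
        g = log(r) - aP * r - lnrref;
        if (fabs(g) < 4e-16) return r;
        if (g > 0.0) hi = r; else lo = r;
        gp = 1.0 / r - aP;
        r -= g / gp;
        if (!(r > lo && r < hi)) r = 0.5 * (lo + hi);
    }
    return r;
}

void cscgm_fast_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const int n_comp = (int) fp[0];
    const double L_p = fp[1], nu = fp[2], d = fp[3], Pi_ct = fp[4],
                 k_u = fp[5], k_c = fp[6], c_e = fp[7], RT = fp[8];
    const double Pi = y[2];
    double r[3], G_tot = 0.0, V_t_tot = 0.0, sumA = 0.0, sumB_rref = 0.0;
    int j;

    const double fm = (Pi >= Pi_ct) ? (Pi - Pi_ct) : 0.0;

    for (j = 0; j < n_comp; j++) {
        const double a = (1.0 - nu) / (2.0 * d * fp[11 + 3 * j + 1]);
        const double r0 = warm_ok ? warm_r[j] : 1.2 * exp(y[3 + j]);
        const double rj = wall_radius(y[3 + j], a * Pi, r0);
        if (rj < 0.0)
            error("coupled model: no mechanical equilibrium (elastic runaway at Pi = %g Pa)", Pi);
        r[j] = rj;
        warm_r[j] = rj;
        const double denom = 1.0 - a * Pi * rj;
        const double dlnrref = fp[11 + 3 * j] * rj / (2.0 * d) * fm;
        ydot[3 + j] = dlnrref;
        sumA += FOUR_PI * a * rj * rj * rj * rj / denom;
        sumB_rref += FOUR_PI * rj * rj * rj / denom * dlnrref;
        G_tot += FOUR_PI * rj * rj;
        V_t_tot += FOUR_PI / 3.0 * rj * rj * rj;
    }
    warm_ok = 1;

    const double c = y[1] / y[0];
    ydot[0] = -L_p * G_tot * (Pi + c_e * RT - c * RT);
    ydot[1] = k_u * G_tot - k_c * V_t_tot;
    ydot[2] = (ydot[0] - sumB_rref) / sumA;

    if (ip[0] >= n_comp)
        for (j = 0; j < n_comp; j++) yout[j] = r[j];
}

/* ---------------- coupled mother + up to two buds ----------------------- */

/* parms: 0 n_comp, 1 L_p, 2 nu, 3 d, 4 Pi_ct, 5 k_u, 6 k_c, 7 c_e, 8 RT,
 *        9 L_x, 10 k_x, 11.. per compartment j: phi_j, E_j, V_b_j
 * state: per compartment j (mother first): V_os, Pi_t, c_i, ln_rref
 */
static double cp[20];

void cscgm_init(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, cp);
}

void cscgm_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const int n_comp = (int) cp[0];
    const double L_p = cp[1], nu = cp[2], d = cp[3], Pi_ct = cp[4],
                 k_u = cp[5], k_c = cp[6], c_e = cp[7], RT = cp[8],
                 L_x = cp[9], k_x = cp[10];

    double r[3], G[3], Pi_i[3], dV[3], Phix[3];
    const double Pi_e = c_e * RT;
    int j;

    for (j = 0; j < n_comp; j++) {
        const double V_os = y[4 * j + 0], c_i = y[4 * j + 2];
        const double V_t = V_os + cp[11 + 3 * j + 2];
        r[j] = cbrt(3.0 * V_t / FOUR_PI);
        G[j] = FOUR_PI * r[j] * r[j];
        Pi_i[j] = c_i * RT;
        dV[j] = -L_p * G[j] * (y[4 * j + 1] + Pi_e - Pi_i[j]);
        Phix[j] = 0.0;
    }

    /* exchange between the mother (j = 0) and each bud; water follows the
     * water-potential difference (Pi_t - Pi_i), osmolytes the concentration
     * difference; both antisymmetric so amounts are conserved */
    for (j = 1; j < n_comp; j++) {
        const double Jx = L_x * ((y[1] - Pi_i[0]) - (y[4 * j + 1] - Pi_i[j]));
        const double Px = k_x * (y[2] - y[4 * j + 2]);
        dV[0] -= Jx;
        dV[j] += Jx;
        Phix[0] -= Px;
        Phix[j] += Px;
    }

    for (j = 0; j < n_comp; j++) {
        const double V_os = y[4 * j + 0], Pi_t = y[4 * j + 1],
                     c_i = y[4 * j + 2];
        const double phi = cp[11 + 3 * j + 0], E = cp[11 + 3 * j + 1],
                     V_b = cp[11 + 3 * j + 2];
        const double V_t = V_os + V_b;
        const double rdot = dV[j] / G[j];

        const double dc = (k_u * G[j] - k_c * V_t + Phix[j]) / V_os
                          - c_i * dV[j] / V_os;

        const double fm = (Pi_t >= Pi_ct) ? (Pi_t - Pi_ct) : 0.0;
        double dPi = 2.0 * E * d / (1.0 - nu) * rdot / (r[j] * r[j])
                     - Pi_t * rdot / r[j]
                     - E * phi / (1.0 - nu) * fm;
        if (Pi_t <= 0.0 && dPi < 0.0) dPi = 0.0;

        ydot[4 * j + 0] = dV[j];
        ydot[4 * j + 1] = dPi;
        ydot[4 * j + 2] = dc;
        ydot[4 * j + 3] = phi * r[j] / (2.0 * d) * fm;
    }
}
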