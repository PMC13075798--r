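/* Compiled dynamics for the laminar neural mass model (LaNMM).
 *
 * The model couples a Jansen-Rit circuit (deep layer: pyramidal P1,
 * spiny stellate SS, somatostatin SST) with a PING circuit
 * (superficial layer: pyramidal P2, parvalbumin PV).  Each synapse is a
 * second-order kernel block  y'' = A a sigma(v) - 2 a y' - a^2 y, so the
 * single column is a 10-dimensional ODE with states
 *   y1..y5  : postsynaptic potentials (mV)
 *   y6..y10 : their time derivatives (mV/s)
 *
 * Parameter vector layout (shared by all single-column entry points):
 *   [0] A_AMPA   [1] a_AMPA   [2] A_GABAs  [3] a_GABAs
 *   [4] A_GABAf  [5] a_GABAf  [6..18] C1..C13
 *   [19] v0      [20] v0_P2   [21] phi0    [22] r
 *   [23] phi_e1  [24] phi_e2  [25] K (tangent columns, variational only)
 *
 * Two-column layout: [0..22] as above, [23] phi (shared external input),
 *   [24] g_ff (P12->P22), [25] g_fb->P11, [26] g_fb->P12, [27] g_fb->SST11
 *
 * External inputs are firing rates (1/s); they enter the sigmoid argument
 * converted to a steady AMPA potential, rate * A_AMPA / a_AMPA (mV).
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define NP_SINGLE 25
#define NP_VAR    26
#define NP_TWOCOL 28
#define NP_MAX    32

static double parms[NP_MAX];

void lanmm_initmod(void (*odeparms)(int *, double *))
{
    int N = NP_SINGLE;
    odeparms(&N, parms);
}

void lanmm_initmod_var(void (*odeparms)(int *, double *))
{
    int N = NP_VAR;
    odeparms(&N, parms);
}

void lanmm_initmod_twocol(void (*odeparms)(int *, double *))
{
    int N = NP_TWOCOL;
    odeparms(&N, parms);
}

/* logistic sigmoid, overflow-safe */
static double sigm(double v, double v0, double phi0, double r)
{
    double x = r * (v0 - v);
    if (x > 700.0) return 0.0;
    return 2.0 * phi0 / (1.0 + exp(x));
}

/* d sigma / d v = r * s * (1 - s / (2 phi0)) */
static double dsigm(double v, double v0, double phi0, double r)
{
    double s = sigm(v, v0, phi0, r);
    return r * s * (1.0 - s / (2.0 * phi0));
}

/* single-column vector field; p points at a NP_SINGLE-layout vector */
static void rhs_single(const double *p, const double *y, double *dy)
{
    const double AA = p[0], aA = p[1], AGs = p[2], aGs = p[3],
        AGf = p[4], aGf = p[5];
    const double *C = p + 6;            /* C[0] = C1 ... C[12] = C13 */
    const double v0 = p[19], v0p2 = p[20], phi0 = p[21], r = p[22];
    const double kin = AA / aA;         /* rate -> potential gain */
    double a1, a2, a3, a4, a5;

    a1 = C[0]*y[1] + C[1]*y[2] + C[2]*kin*p[23] + C[10]*y[3];
    a2 = C[3]*y[0];
    a3 = C[4]*y[0];
    a4 = C[5]*y[3] + C[6]*y[4] + C[7]*kin*p[24] + C[11]*y[0];
    a5 = C[8]*y[3] + C[9]*y[4] + C[12]*y[0];

    dy[0] = y[5];
    dy[1] = y[6];
    dy[2] = y[7];
    dy[3] = y[8];
    dy[4] = y[9];
    dy[5] = aA*AA*sigm(a1, v0, phi0, r)    - 2.0*aA*y[5]  - aA*aA*y[0];
    dy[6] = aA*AA*sigm(a2, v0, phi0, r)    - 2.0*aA*y[6]  - aA*aA*y[1];
    dy[7] = aGs*AGs*sigm(a3, v0, phi0, r)  - 2.0*aGs*y[7] - aGs*aGs*y[2];
    dy[8] = aA*AA*sigm(a4, v0p2, phi0, r)  - 2.0*aA*y[8]  - aA*aA*y[3];
    dy[9] = aGf*AGf*sigm(a5, v0, phi0, r)  - 2.0*aGf*y[9] - aGf*aGf*y[4];
}

/* dense 10x10 Jacobian, column-major J[i + 10*j] = d f_i / d y_j */
static void jac_single(const double *p, const double *y, double *J)
{
    const double AA = p[0], aA = p[1], AGs = p[2], aGs = p[3],
        AGf = p[4], aGf = p[5];
    const double *C = p + 6;
    const double v0 = p[19], v0p2 = p[20], phi0 = p[21], r = p[22];
    const double kin = AA / aA;
    double a1, a4, a5, g1, g2, g3, g4, g5;
    int i;

    for (i = 0; i < 100; i++) J[i] = 0.0;
    for (i = 0; i < 5; i++) J[i + 10*(i+5)] = 1.0;

    a1 = C[0]*y[1] + C[1]*y[2] + C[2]*kin*p[23] + C[10]*y[3];
    a4 = C[5]*y[3] + C[6]*y[4] + C[7]*kin*p[24] + C[11]*y[0];
    a5 = C[8]*y[3] + C[9]*y[4] + C[12]*y[0];

    g1 = aA*AA*dsigm(a1, v0, phi0, r);
    g2 = aA*AA*dsigm(C[3]*y[0], v0, phi0, r);
    g3 = aGs*AGs*dsigm(C[4]*y[0], v0, phi0, r);
    g4 = aA*AA*dsigm(a4, v0p2, phi0, r);
    g5 = aGf*AGf*dsigm(a5, v0, phi0, r);

    J[5 + 10*1] = g1*C[0];  J[5 + 10*2] = g1*C[1];  J[5 + 10*3] = g1*C[10];
    J[5 + 10*0] = -aA*aA;   J[5 + 10*5] = -2.0*aA;

    J[6 + 10*0] = g2*C[3];  J[6 + 10*1] = -aA*aA;   J[6 + 10*6] = -2.0*aA;

    J[7 + 10*0] = g3*C[4];  J[7 + 10*2] = -aGs*aGs; J[7 + 10*7] = -2.0*aGs;

    J[8 + 10*3] = g4*C[5] - aA*aA;  J[8 + 10*4] = g4*C[6];
    J[8 + 10*0] = g4*C[11];         J[8 + 10*8] = -2.0*aA;

    J[9 + 10*3] = g5*C[8];  J[9 + 10*4] = g5*C[9] - aGf*aGf;
    J[9 + 10*0] = g5*C[12]; J[9 + 10*9] = -2.0*aGf;
}

/* deSolve entry point: single column */
void lanmm_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    rhs_single(parms, y, ydot);
}

/* deSolve entry point: flow plus K tangent columns (variational system).
 * State layout: y[0..9] flow, then K columns of 10 each. */
void lanmm_derivs_var(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    int K = (int) parms[25];
    double J[100];
    int k, i, j;

    rhs_single(parms, y, ydot);
    jac_single(parms, y, J);
    for (k = 0; k < K; k++) {
        const double *v = y + 10 + 10*k;
        double *dv = ydot + 10 + 10*k;
        for (i = 0; i < 10; i++) {
            double s = 0.0;
            for (j = 0; j < 10; j++) s += J[i + 10*j] * v[j];
            dv[i] = s;
        }
    }
}

/* two-column model: column 1 = low-level area, column 2 = high-level.
 * Feedforward P12 -> P22; feedback P21 -> {P11, P12, SST11}.
 * Long-range firing rates enter the target sigmoid argument scaled by
 * the steady AMPA gain A/a, like the external input phi. */
static void rhs_twocol(const double *p, const double *y, double *dy)
{
    const double AA = p[0], aA = p[1], AGs = p[2], aGs = p[3],
        AGf = p[4], aGf = p[5];
    const double *C = p + 6;
    const double v0 = p[19], v0p2 = p[20], phi0 = p[21], r = p[22];
    const double phi = p[23];
    const double gff = p[24], gp11 = p[25], gp12 = p[26], gsst = p[27];
    const double kin = AA / aA;
    const double *y1 = y, *y2 = y + 10;
    double *d1 = dy, *d2 = dy + 10;
    double a, r_p21, r_p12;

    /* column 2 deep pyramidal P21: no incoming long-range input */
    a = C[0]*y2[1] + C[1]*y2[2] + C[2]*kin*phi + C[10]*y2[3];
    r_p21 = sigm(a, v0, phi0, r);
    d2[0] = y2[5];
    d2[5] = aA*AA*r_p21 - 2.0*aA*y2[5] - aA*aA*y2[0];

    /* column 1 deep pyramidal P11: feedback from P21 */
    a = C[0]*y1[1] + C[1]*y1[2] + C[2]*kin*phi + C[10]*y1[3]
        + gp11*kin*r_p21;
    d1[0] = y1[5];
    d1[5] = aA*AA*sigm(a, v0, phi0, r) - 2.0*aA*y1[5] - aA*aA*y1[0];

    /* spiny stellate blocks (intra-column only) */
    d1[1] = y1[6];
    d1[6] = aA*AA*sigm(C[3]*y1[0], v0, phi0, r) - 2.0*aA*y1[6] - aA*aA*y1[1];
    d2[1] = y2[6];
    d2[6] = aA*AA*sigm(C[3]*y2[0], v0, phi0, r) - 2.0*aA*y2[6] - aA*aA*y2[1];

    /* SST blocks; SST11 receives feedback from P21 */
    d1[2] = y1[7];
    d1[7] = aGs*AGs*sigm(C[4]*y1[0] + gsst*kin*r_p21, v0, phi0, r)
        - 2.0*aGs*y1[7] - aGs*aGs*y1[2];
    d2[2] = y2[7];
    d2[7] = aGs*AGs*sigm(C[4]*y2[0], v0, phi0, r)
        - 2.0*aGs*y2[7] - aGs*aGs*y2[2];

    /* superficial pyramidal P12: feedback from P21 */
    a = C[5]*y1[3] + C[6]*y1[4] + C[7]*kin*phi + C[11]*y1[0]
        + gp12*kin*r_p21;
    r_p12 = sigm(a, v0p2, phi0, r);
    d1[3] = y1[8];
    d1[8] = aA*AA*r_p12 - 2.0*aA*y1[8] - aA*aA*y1[3];

    /* superficial pyramidal P22: feedforward from P12 */
    a = C[5]*y2[3] + C[6]*y2[4] + C[7]*kin*phi + C[11]*y2[0]
        + gff*kin*r_p12;
    d2[3] = y2[8];
    d2[8] = aA*AA*sigm(a, v0p2, phi0, r) - 2.0*aA*y2[8] - aA*aA*y2[3];

    /* PV blocks (intra-column only) */
    d1[4] = y1[9];
    d1[9] = aGf*AGf*sigm(C[8]*y1[3] + C[9]*y1[4] + C[12]*y1[0], v0, phi0, r)
        - 2.0*aGf*y1[9] - aGf*aGf*y1[4];
    d2[4] = y2[9];
    d2[9] = aGf*AGf*sigm(C[8]*y2[3] + C[9]*y2[4] + C[12]*y2[0], v0, phi0, r)
        - 2.0*aGf*y2[9] - aGf*aGf*y2[4];
}

void lanmm_derivs_twocol(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    rhs_twocol(parms, y, ydot);
}

/* ------------------------------------------------------------------ */
/* Benettin algorithm, two largest Lyapunov exponents, fixed-step RK4 on
 * the 30-dimensional variational system with periodic Gram-Schmidt
 * renormalization.  Returns c(l1, l2, block l1 estimates, block l2). */

static void deriv30(const double *p, const double *y, double *dy)
{
    double J[100];
    int k, i, j;

    rhs_single(p, y, dy);
    jac_single(p, y, J);
    for (k = 0; k < 2; k++) {
        const double *v = y + 10 + 10*k;
        double *dv = dy + 10 + 10*k;
        for (i = 0; i < 10; i++) {
            double s = 0.0;
            for (j = 0; j < 10; j++) s += J[i + 10*j] * v[j];
            dv[i] = s;
        }
    }
}

static void rk4_step30(const double *p, double *y, double dt)
{
    double k1[30], k2[30], k3[30], k4[30], tmp[30];
    int i;

    deriv30(p, y, k1);
    for (i = 0; i < 30; i++) tmp[i] = y[i] + 0.5*dt*k1[i];
    deriv30(p, tmp, k2);
    for (i = 0; i < 30; i++) tmp[i] = y[i] + 0.5*dt*k2[i];
    deriv30(p, tmp, k3);
    for (i = 0; i < 30; i++) tmp[i] = y[i] + dt*k3[i];
    deriv30(p, tmp, k4);
    for (i = 0; i < 30; i++)
        y[i] += dt*(k1[i] + 2.0*k2[i] + 2.0*k3[i] + k4[i])/6.0;
}

static void rk4_step10(const double *p, double *y, double dt)
{
    double k1[10], k2[10], k3[10], k4[10], tmp[10];
    int i;

    rhs_single(p, y, k1);
    for (i = 0; i < 10; i++) tmp[i] = y[i] + 0.5*dt*k1[i];
    rhs_single(p, tmp, k2);
    for (i = 0; i < 10; i++) tmp[i] = y[i] + 0.5*dt*k2[i];
    rhs_single(p, tmp, k3);
    for (i = 0; i < 10; i++) tmp[i] = y[i] + dt*k3[i];
    rhs_single(p, tmp, k4);
    for (i = 0; i < 10; i++)
        y[i] += dt*(k1[i] + 2.0*k2[i] + 2.0*k3[i] + k4[i])/6.0;
}

SEXP lanmm_benettin_c(SEXP sy0, SEXP sparms, SEXP sdt, SEXP sttrans,
                      SEXP staccum, SEXP strenorm, SEXP snblock,
                      SEXP stwarm)
{
    const double *p = REAL(sparms);
    double dt = asReal(sdt), ttrans = asReal(sttrans),
        taccum = asReal(staccum), trenorm = asReal(strenorm),
        twarm = asReal(stwarm);
    int nblock = asInteger(snblock);
    double y[30];
    int i, k, b;
    long nseg, steps_per_seg, s;
    double sum1 = 0.0, sum2 = 0.0, t_used = 0.0;
    SEXP res;
    double *r;

    for (i = 0; i < 10; i++) y[i] = REAL(sy0)[i];

    /* transient on the flow only */
    {
        long nt = (long) ceil(ttrans / dt);
        for (s = 0; s < nt; s++) rk4_step10(p, y, dt);
    }
    for (i = 0; i < 10; i++) {
        if (!R_FINITE(y[i])) error("trajectory blow-up during transient");
    }

    /* orthonormal tangent seed */
    for (i = 10; i < 30; i++) y[i] = 0.0;
    y[10] = 1.0; y[21] = 1.0;

    steps_per_seg = (long) ceil(trenorm / dt);

    /* tangent warm-up: renormalize but discard the stretch factors so
     * the tangent frame aligns with the Oseledets directions before
     * accumulation starts */
    {
        long nw = (long) ceil(twarm / trenorm);
        long w, q;
        for (w = 0; w < nw; w++) {
            double n1 = 0.0, dot = 0.0, n2 = 0.0;
            for (q = 0; q < steps_per_seg; q++) rk4_step30(p, y, dt);
            for (i = 0; i < 10; i++) n1 += y[10+i]*y[10+i];
            n1 = sqrt(n1);
            for (i = 0; i < 10; i++) y[10+i] /= n1;
            for (i = 0; i < 10; i++) dot += y[10+i]*y[20+i];
            for (i = 0; i < 10; i++) y[20+i] -= dot*y[10+i];
            for (i = 0; i < 10; i++) n2 += y[20+i]*y[20+i];
            n2 = sqrt(n2);
            for (i = 0; i < 10; i++) y[20+i] /= n2;
        }
    }
    nseg = (long) ceil(taccum / trenorm);
    if (nseg < nblock) nblock = (int) nseg;

    res = PROTECT(allocVector(REALSXP, 2 + 2*nblock));
    r = REAL(res);
    for (i = 0; i < 2 + 2*nblock; i++) r[i] = 0.0;

    {
        long seg_per_block = nseg / nblock;
        double bsum1 = 0.0, bsum2 = 0.0, bt = 0.0;
        b = 0;
        for (s = 0; s < nseg; s++) {
            long q;
            double n1, dot, n2, seg_t = steps_per_seg * dt;
            for (q = 0; q < steps_per_seg; q++) rk4_step30(p, y, dt);
            for (i = 0; i < 10; i++)
                if (!R_FINITE(y[i])) error("trajectory blow-up");
            /* Gram-Schmidt on the two tangent vectors */
            n1 = 0.0;
            for (i = 0; i < 10; i++) n1 += y[10+i]*y[10+i];
            n1 = sqrt(n1);
            for (i = 0; i < 10; i++) y[10+i] /= n1;
            dot = 0.0;
            for (i = 0; i < 10; i++) dot += y[10+i]*y[20+i];
            for (i = 0; i < 10; i++) y[20+i] -= dot*y[10+i];
            n2 = 0.0;
            for (i = 0; i < 10; i++) n2 += y[20+i]*y[20+i];
            n2 = sqrt(n2);
            for (i = 0; i < 10; i++) y[20+i] /= n2;

            sum1 += log(n1); sum2 += log(n2); t_used += seg_t;
            bsum1 += log(n1); bsum2 += log(n2); bt += seg_t;
            if (b < nblock && (s + 1) % seg_per_block == 0) {
                r[2 + b] = bsum1 / bt;
                r[2 + nblock + b] = bsum2 / bt;
                bsum1 = bsum2 = bt = 0.0;
                b++;
            }
        }
    }
    r[0] = sum1 / t_used;
    r[1] = sum2 / t_used;
    UNPROTECT(1);
    return res;
}

/* registration */
#include <R_ext/Rdynload.h>

static const R_CallMethodDef call_entries[] = {
    {"lanmm_benettin_c", (DL_FUNC) &lanmm_benettin_c, 8},
    {NULL, NULL, 0}
};

void R_init_lanmm(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* deSolve looks up derivs/initmod symbols by name */
    R_useDynamicSymbols(dll, TRUE);
}
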