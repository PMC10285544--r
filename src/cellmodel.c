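/* Electro-mechanical ventricular cardiomyocyte model.
 *
 * Electrophysiology follows the ten Tusscher-Panfilov 2006 human ventricular
 * formulation, with the SR calcium release replaced by a four-state Markov
 * ryanodine-receptor gate (R/O/I/RI) whose release scale (ks) and two rate
 * constants (kim, kom) are exposed as scalable parameters.  A minimal
 * contractile block (CaTnC kinetics with cooperativity, cross-bridge fraction,
 * contractile element in series with an exponential series-elastic element and
 * in parallel with an exponential parallel-elastic element) closes the
 * mechano-calcium-electric loop through the troponin buffering term in the
 * cytosolic Ca2+ equation.
 *
 * Compiled-model interface for deSolve: cell_initmod / cell_derivs plus two
 * root functions used for afterload switching.
 *
 * State vector (24):
 *  0 V      membrane potential, mV
 *  1 m  2 h  3 j        fast Na+ gates
 *  4 d  5 f  6 f2  7 fcass   L-type Ca2+ gates
 *  8 r  9 s             transient outward gates
 * 10 xs                 IKs gate
 * 11 xr1 12 xr2         IKr gates
 * 13 Nai 14 Ki          mM
 * 15 Cai 16 Cass 17 Casr  mM
 * 18 O  19 I  20 RI     RyR Markov states (R = 1 - O - I - RI)
 * 21 B                  CaTnC concentration, mM
 * 22 N                  attached cross-bridge fraction
 * 23 lc                 contractile-element length, fraction of L_max
 */

#include <R.h>
#include <math.h>

#define N_PARMS 45
static double p[N_PARMS];

/* parameter slots (kept in sync with R side, see cell-model.R) */
#define SC_GNA    p[0]
#define SC_GCAL   p[1]
#define SC_GK1    p[2]
#define SC_GKS    p[3]
#define SC_GKR    p[4]
#define SC_VMAXUP p[5]
#define SC_KNACA  p[6]
#define SC_PNAK   p[7]
#define SC_KS     p[8]
#define SC_KIM    p[9]
#define SC_KOM    p[10]
#define STIM_AMP  p[11]
#define STIM_ON   p[12]
#define MODE      p[13]   /* 0 isometric, 1 isotonic (afterloaded) */
#define L_CELL    p[14]   /* imposed length (isometric) / initial length */
#define F_CLAMP   p[15]   /* clamped total force during isotonic phase */
#define BLOCK_CA  p[16]   /* 1: zero all sarcolemmal Ca fluxes (conservation check) */
#define BETA_SE   p[17]
#define ALPHA_SE  p[18]
#define BETA_PE   p[19]
#define ALPHA_PE  p[20]
#define L_PE0     p[21]
#define F_XB      p[22]
#define V_H       p[23]
#define A_H       p[24]
#define EPS_F     p[25]
#define K_P       p[26]
#define K_M       p[27]
#define C_V       p[28]
#define S_OV      p[29]
#define L_HALF    p[30]
#define A_ON      p[31]
#define A_OFF     p[32]
#define K_COOP    p[33]
#define C_BB      p[34]
#define B_TOT     p[35]
#define B_50      p[36]
#define N_HILL    p[37]
#define GTO       p[38]
#define GKS_B     p[39]
#define KS_BASE   p[40]
#define KIM_BASE  p[41]
#define KOM_BASE  p[42]
#define K1_PRIME  p[43]
#define K2_PRIME  p[44]

/* fixed physical constants (ten Tusscher-Panfilov 2006) */
static const double Rgas = 8314.472, Temp = 310.0, Frdy = 96485.3415;
static const double Cm = 0.185;
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Ko = 5.4, Nao = 140.0, Cao = 2.0;
static const double GNa = 14.838, GK1 = 5.405, GKr = 0.153;
static const double GCaL = 3.98e-5, GbNa = 0.00029, GbCa = 0.000592;
static const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
static const double PNaK = 2.724, KmK = 1.0, KmNa = 40.0;
static const double kNaCa = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
                    gam = 0.35, alpNCX = 2.5;
static const double Vmaxup = 0.012, Kup = 0.00025, Vleak = 0.00015,
                    Vxfer = 0.005;
static const double maxsr = 8.0, minsr = 1.0, EC50sr = 3.5;
static const double Bufc = 0.35, Kbufc = 0.001, Bufsr = 5.0, Kbufsr = 0.3,
                    Bufss = 0.4, Kbufss = 0.00025;
static const double pKNa = 0.03;

void cell_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

/* series-elastic force from strain */
static double f_se(double strain)
{
    return BETA_SE * expm1(ALPHA_SE * strain);
}

/* parallel-elastic force at cell length L */
static double f_pe(double L)
{
    double s = L - L_PE0;
    return (s > 0.0) ? BETA_PE * expm1(ALPHA_PE * s) : 0.0;
}

/* cell length in the isotonic phase: solve F_se(L - lc) + F_pe(L) = F_clamp */
static double solve_length(double lc)
{
    double L = lc + log1p(F_CLAMP / BETA_SE) / ALPHA_SE; /* SE-only guess */
    for (int it = 0; it < 30; it++) {
        double s = L - L_PE0;
        double fpe = (s > 0.0) ? BETA_PE * expm1(ALPHA_PE * s) : 0.0;
        double dpe = (s > 0.0) ? BETA_PE * ALPHA_PE * exp(ALPHA_PE * s) : 0.0;
        double fse = f_se(L - lc);
        double dse = BETA_SE * ALPHA_SE * exp(ALPHA_SE * (L - lc));
        double h = fse + fpe - F_CLAMP;
        double step = h / (dse + dpe);
        L -= step;
        if (fabs(step) < 1e-13) break;
    }
    return L;
}

/* mechanics auxiliaries shared by derivs and root functions */
static void mech_aux(const double *y, double *Lout, double *Fse, double *Ftot,
                     double *vout)
{
    double Nxb = y[22], lc = y[23];
    double L, fse;

    if (MODE > 0.5) {
        L = solve_length(lc);
        fse = F_CLAMP - f_pe(L);
    } else {
        L = L_CELL;
        fse = f_se(L - lc);
    }
    double rho = fse / (F_XB * Nxb + EPS_F);
    if (rho < 0.0) rho = 0.0;
    double v = V_H * (rho - 1.0) / (rho + A_H);

    *Lout = L;
    *Fse = fse;
    *Ftot = fse + f_pe(L);
    *vout = v;
}

void cell_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
                 int *ip)
{
    double V = y[0], m = y[1], h = y[2], j = y[3];
    double d = y[4], f = y[5], f2 = y[6], fcass = y[7];
    double r = y[8], s = y[9], xs = y[10], xr1 = y[11], xr2 = y[12];
    double Nai = y[13], Ki = y[14];
    double Cai = y[15], Cass = y[16], Casr = y[17];
    double O = y[18], Iry = y[19], RI = y[20];
    double B = y[21], Nxb = y[22];

    if (Cai < 1e-9) Cai = 1e-9;
    if (Cass < 1e-9) Cass = 1e-9;
    if (Casr < 1e-9) Casr = 1e-9;

    const double rtf = Rgas * Temp / Frdy;
    double EK = rtf * log(Ko / Ki);
    double ENa = rtf * log(Nao / Nai);
    double EKs = rtf * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
    double ECa = 0.5 * rtf * log(Cao / Cai);

    /* ---- ionic currents ---- */
    double INa = SC_GNA * GNa * m * m * m * h * j * (V - ENa);

    double vf = (V - 15.0) * Frdy / (Rgas * Temp);
    double e2vf = exp(2.0 * vf);
    double ICaL;
    if (fabs(vf) < 1e-6) {
        ICaL = SC_GCAL * GCaL * d * f * f2 * fcass * 2.0 * Frdy *
               (0.25 * Cass - Cao);
    } else {
        ICaL = SC_GCAL * GCaL * d * f * f2 * fcass * 4.0 * (V - 15.0) *
               Frdy * Frdy / (Rgas * Temp) *
               (0.25 * Cass * e2vf - Cao) / (e2vf - 1.0);
    }

    double Ito = GTO * r * s * (V - EK);
    double IKs = SC_GKS * GKS_B * xs * xs * (V - EKs);
    double IKr = SC_GKR * GKr * sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);

    double aK1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
    double bK1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) +
                  exp(0.1 * (V - EK - 10.0))) /
                 (1.0 + exp(-0.5 * (V - EK)));
    double xK1 = aK1 / (aK1 + bK1);
    double IK1 = SC_GK1 * GK1 * sqrt(Ko / 5.4) * xK1 * (V - EK);

    double vfrt = V * Frdy / (Rgas * Temp);
    double INaCa = SC_KNACA * kNaCa *
        (exp(gam * vfrt) * Nai * Nai * Nai * Cao -
         exp((gam - 1.0) * vfrt) * Nao * Nao * Nao * Cai * alpNCX) /
        ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
         (1.0 + ksat * exp((gam - 1.0) * vfrt)));

    double INaK = SC_PNAK * PNaK * Ko * Nai /
        ((Ko + KmK) * (Nai + KmNa) *
         (1.0 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt)));

    double IpCa = GpCa * Cai / (Cai + KpCa);
    double IpK = GpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
    double IbNa = GbNa * (V - ENa);
    double IbCa = GbCa * (V - ECa);

    if (BLOCK_CA > 0.5) {
        ICaL = 0.0;
        IbCa = 0.0;
        IpCa = 0.0;
        INaCa = 0.0;
    }

    double Istim = (STIM_ON > 0.5) ? STIM_AMP : 0.0;

    ydot[0] = -(IK1 + Ito + IKr + IKs + ICaL + INaK + INa + IbNa + INaCa +
                IbCa + IpK + IpCa + Istim);

    /* ---- gating ---- */
    double minf = 1.0 / ((1.0 + exp((-56.86 - V) / 9.03)) *
                         (1.0 + exp((-56.86 - V) / 9.03)));
    double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + exp((V - 50.0) / 200.0));
    ydot[1] = (minf - m) / (am * bm);

    double hinf = 1.0 / ((1.0 + exp((V + 71.55) / 7.43)) *
                         (1.0 + exp((V + 71.55) / 7.43)));
    double ah, bh;
    if (V >= -40.0) {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
    } else {
        ah = 0.057 * exp(-(V + 80.0) / 6.8);
        bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
    }
    ydot[2] = (hinf - h) * (ah + bh);

    double aj, bj;
    if (V >= -40.0) {
        aj = 0.0;
        bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    } else {
        aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
             (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        bj = 0.02424 * exp(-0.01052 * V) /
             (1.0 + exp(-0.1378 * (V + 40.14)));
    }
    ydot[3] = (hinf - j) * (aj + bj);

    double dinf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
    double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    ydot[4] = (dinf - d) / (ad * bd + gd);

    double finf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
    double tauf = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                  200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
                  180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
    ydot[5] = (finf - f) / tauf;

    double f2inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
    double tauf2 = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                   31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
                   80.0 / (1.0 + exp((V + 30.0) / 10.0));
    ydot[6] = (f2inf - f2) / tauf2;

    double css = Cass / 0.05;
    double fcinf = 0.6 / (1.0 + css * css) + 0.4;
    double taufc = 80.0 / (1.0 + css * css) + 2.0;
    ydot[7] = (fcinf - fcass) / taufc;

    double rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
    double taur = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    ydot[8] = (rinf - r) / taur;

    /* endocardial s-gate kinetics (soft notch) */
    double sinf = 1.0 / (1.0 + exp((V + 28.0) / 5.0));
    double taus = 1000.0 * exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
    ydot[9] = (sinf - s) / taus;

    double xsinf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
    double axs = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
    double bxs = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
    ydot[10] = (xsinf - xs) / (axs * bxs + 80.0);

    double xr1inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
    double axr1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
    double bxr1 = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
    ydot[11] = (xr1inf - xr1) / (axr1 * bxr1);

    double xr2inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
    double axr2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
    double bxr2 = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
    ydot[12] = (xr2inf - xr2) / (axr2 * bxr2);

    /* ---- RyR Markov gate ---- */
    double ecr = (EC50sr / Casr) * (EC50sr / Casr);
    double kcasr = maxsr - (maxsr - minsr) / (1.0 + ecr * ecr);
    double ko = (K1_PRIME / kcasr) * Cass * Cass;        /* R->O trigger */
    double ki = K2_PRIME * kcasr * Cass;                 /* O->I inactivation */
    double kom = SC_KOM * KOM_BASE;                      /* O->R and I->RI */
    /* refractoriness: recovery to the closed-available state is inhibited
       while subspace Ca2+ is elevated, so the gate cannot re-fire within the
       same release episode */
    double cgate = Cass / 0.0005;
    double kim = SC_KIM * KIM_BASE / (1.0 + cgate * cgate);

    double Rst = 1.0 - O - Iry - RI;

    /* monotone chain R->O->I->RI->R: recovery never feeds the open state
       directly, so release terminates once availability is spent */
    ydot[18] = ko * Rst - (kom + ki) * O;                        /* dO  */
    ydot[19] = ki * O - kom * Iry;                               /* dI  */
    ydot[20] = kom * Iry - kim * RI;                             /* dRI */

    double Irel = SC_KS * KS_BASE * O * (Casr - Cass);
    double Ileak = Vleak * (Casr - Cai);
    double Iup = SC_VMAXUP * Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
    double Ixfer = Vxfer * (Cass - Cai);

    /* ---- mechanics ---- */
    double L, Fse, Ftot, v;
    mech_aux(y, &L, &Fse, &Ftot, &v);

    double ovl = 1.0 / (1.0 + exp(-S_OV * (y[23] - L_HALF)));
    double bfrac = B / B_TOT;
    double act = pow(bfrac, N_HILL) /
                 (pow(bfrac, N_HILL) + pow(B_50, N_HILL));
    double gv = 1.0 + C_V * fmax(-v, 0.0) / V_H;
    ydot[22] = K_P * ovl * act * (1.0 - Nxb) - K_M * gv * Nxb;

    double pi_nb = exp(-K_COOP * (Nxb + C_BB * bfrac));
    double dB = A_ON * Cai * (B_TOT - B) - A_OFF * pi_nb * B;
    ydot[21] = dB;
    ydot[23] = v;

    /* ---- concentrations ---- */
    double caibufc = 1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
    double casrbuf = 1.0 / (1.0 + Bufsr * Kbufsr / ((Casr + Kbufsr) * (Casr + Kbufsr)));
    double cassbuf = 1.0 / (1.0 + Bufss * Kbufss / ((Cass + Kbufss) * (Cass + Kbufss)));

    ydot[15] = caibufc *
        ((-(IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * Frdy)) +
         (Ileak - Iup) * Vsr / Vc + Ixfer - dB);
    ydot[16] = cassbuf *
        (-ICaL * Cm / (2.0 * Vss * Frdy) + Irel * Vsr / Vss -
         Ixfer * Vc / Vss);
    ydot[17] = casrbuf * (Iup - Irel - Ileak);

    ydot[13] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm / (Vc * Frdy);
    ydot[14] = -(Istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * Cm /
               (Vc * Frdy);

    if (*ip >= 4) {
        yout[0] = Fse;
        yout[1] = Ftot;
        yout[2] = L;
        yout[3] = v;
    }
}

/* root: active force crosses the afterload trigger (isometric phase) */
void cell_root_force(int *neq, double *t, double *y, int *ng, double *gout)
{
    double L, Fse, Ftot, v;
    mech_aux(y, &L, &Fse, &Ftot, &v);
    gout[0] = Fse - F_CLAMP + f_pe(L_CELL); /* active force vs active afterload */
}

/* root: cell length re-attains the initial length (isotonic phase) */
void cell_root_len(int *neq, double *t, double *y, int *ng, double *gout)
{
    double L, Fse, Ftot, v;
    mech_aux(y, &L, &Fse, &Ftot, &v);
    gout[0] = L - L_CELL;
}
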