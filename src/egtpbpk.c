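/* Mass-balance derivatives of the whole-body ergothioneine PBPK model,
 * compiled for use with deSolve (dllname = "egtpbpk").
 *
 * The parameter vector is packed on the R side by .egt_pack_parms(); the
 * order here must stay in lockstep with that function.  Amounts are in
 * umol, concentrations in uM, volumes in L, flows in L/h, time in h.
 *
 * State layout (n = number of tandem liver sub-units):
 *   y[0]                 A_g     gut lumen amount
 *   y[1 .. n]            C_he,j  liver extracellular, units 1..n
 *   y[n+1 .. 2n]         C_h,j   liver intracellular, units 1..n
 *   y[2n+1 .. 2n+6]      C_ae, C_a, C_se, C_s, C_me, C_m
 *   y[2n+7]              C_d     renal proximal duct
 *   y[2n+8]              A_pre   RBC precursor amount
 *   y[2n+9]              C_RBC   circulating RBC
 *   y[2n+10]             C_p     plasma
 *   y[2n+11]             A_u     cumulative urinary excretion (bookkeeping)
 */

#include <R.h>

static double p[34];

#define P_R      p[0]
#define P_KA     p[1]
#define P_VP     p[2]
#define P_VRBC   p[3]
#define P_VA     p[4]
#define P_VAE    p[5]
#define P_VH     p[6]
#define P_VHE    p[7]
#define P_VS     p[8]
#define P_VSE    p[9]
#define P_VM     p[10]
#define P_VME    p[11]
#define P_VD     p[12]
#define P_QA     p[13]
#define P_QH     p[14]
#define P_QS     p[15]
#define P_QM     p[16]
#define P_QU     p[17]
#define P_GFR    p[18]
#define P_K1     p[19]
#define P_KB     p[20]
#define P_VMAXH  p[21]
#define P_VMAXD  p[22]
#define P_VMAXP  p[23]
#define P_KM     p[24]
#define P_NLIV   p[25]
#define P_VMAXA  p[26]
#define P_VMAXS  p[27]
#define P_VMAXM  p[28]
#define P_PSH    p[29]
#define P_PSA    p[30]
#define P_PSS    p[31]
#define P_PSM    p[32]
#define P_PORTAL p[33]   /* 1: absorbed flux enters liver unit 1; 0: plasma */

void egt_initparms(void (*odeparms)(int *, double *))
{
    int N = 34;
    odeparms(&N, p);
}

static double mm(double vmax, double km, double c)
{
    return vmax * c / (km + c);
}

void egt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int n = (int) P_NLIV;
    int o = 1 + 2 * n;

    double Ag   = y[0];
    const double *Che = y + 1;
    const double *Ch  = y + 1 + n;
    double Cae = y[o],     Ca = y[o + 1];
    double Cse = y[o + 2], Cs = y[o + 3];
    double Cme = y[o + 4], Cm = y[o + 5];
    double Cd   = y[o + 6];
    double Apre = y[o + 7];
    double Crbc = y[o + 8];
    double Cp   = y[o + 9];

    double absflux = P_KA * Ag;
    ydot[0] = P_R - absflux;

    /* tandem liver: per-unit volumes, transport maximum and efflux */
    double vhe   = P_VHE / n;
    double vh    = P_VH / n;
    double vmaxh = P_VMAXH / n;
    double psh   = P_PSH / n;
    int j;
    for (j = 0; j < n; j++) {
        double cin = (j == 0) ? Cp : Che[j - 1];
        double up  = mm(vmaxh, P_KM, Che[j]);
        double inj = (j == 0 && P_PORTAL > 0.5) ? absflux : 0.0;
        ydot[1 + j]     = (P_QH * (cin - Che[j]) + inj - up + psh * Ch[j]) / vhe;
        ydot[1 + n + j] = (up - psh * Ch[j]) / vh;
    }

    double upA = mm(P_VMAXA, P_KM, Cae);
    double upS = mm(P_VMAXS, P_KM, Cse);
    double upM = mm(P_VMAXM, P_KM, Cme);
    ydot[o]     = (P_QA * (Cp - Cae) - upA + P_PSA * Ca) / P_VAE;
    ydot[o + 1] = (upA - P_PSA * Ca) / P_VA;
    ydot[o + 2] = (P_QS * (Cp - Cse) - upS + P_PSS * Cs) / P_VSE;
    ydot[o + 3] = (upS - P_PSS * Cs) / P_VS;
    ydot[o + 4] = (P_QM * (Cp - Cme) - upM + P_PSM * Cm) / P_VME;
    ydot[o + 5] = (upM - P_PSM * Cm) / P_VM;

    double upD = mm(P_VMAXD, P_KM, Cd);
    double upP = mm(P_VMAXP, P_KM, Cp);
    ydot[o + 6] = (P_GFR * Cp - upD - P_QU * Cd) / P_VD;
    ydot[o + 7] = upP - P_K1 * Apre;
    ydot[o + 8] = (P_K1 * Apre - P_KB * P_VRBC * Crbc) / P_VRBC;
    ydot[o + 9] = (P_QH * (Che[n - 1] - Cp)
                   + P_QA * (Cae - Cp) + P_QS * (Cse - Cp) + P_QM * (Cme - Cp)
                   - P_GFR * Cp + upD - upP
                   + P_KB * P_VRBC * Crbc
                   + ((P_PORTAL > 0.5) ? 0.0 : absflux)) / P_VP;
    ydot[o + 10] = P_QU * Cd;
}
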