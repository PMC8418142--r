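/* Right-hand side of the open-loop single-ventricle circulation network.
 *
 * Unit system: g-mm-s (pressure Pa, flow mm^3/s, volume mm^3).
 *
 * Topology: constant-pressure right atrium -> tricuspid diode+inductor ->
 * elastance ventricle -> dynamically controlled aortic valve (+ aortic
 * root compliance/inertance) -> upper/lower-body Windkessels in series ->
 * SVC/IVC inlet nodes of the Fontan-pathway surrogate -> confluence ->
 * LPA/RPA Windkessel terminations; optional fenestration branch from the
 * IVC-pathway node to its own Windkessel referenced to atrial pressure.
 *
 * Parameter vector layout (0-based, length NPARMS) and the state layout
 * are mirrored in R/network.R; keep the two in sync.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define NPARMS 60

/* parameter indices */
#define iT        0
#define iEMIN     1
#define iK        2
#define iTAU1     3
#define iM1       4
#define iTAU2     5
#define iM2       6
#define iVREST    7
#define iPRA      8
#define iRTV      9
#define iITV     10
#define iCAR     11
#define iIAR     12
#define iAANN    13
#define iPOPEN   14
#define iPCLOSE  15
#define iKVO     16
#define iKVC     17
#define iMRG     18
#define iMST     19
#define iLEFF    20
#define iRHO     21
#define iKSLIN   22
#define iWK      23  /* 5 beds x (Rp, C, Rd, Pd): ubv, lbv, lpa, rpa, fen */
#define iFEN     43
#define iRSVC    44
#define iLSVC    45
#define iRIVC    46
#define iLIVC    47
#define iRLPA    48
#define iLLPA    49
#define iRRPA    50
#define iLRPA    51
#define iRFEN    52
#define iLFEN    53
#define iCNSVC   54
#define iCNIVC   55
#define iCNCONF  56
#define iFREEZE  57
#define iFORCE   58
#define iCLAMP   59

static double parms[NPARMS];

#define NOUT 9

void circ_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double two_hill(double t)
{
    double tt = fmod(t, parms[iT]);
    double g1, g2;
    if (tt < 0.0) tt += parms[iT];
    if (parms[iFREEZE] > 0.5) return parms[iEMIN];
    g1 = pow(tt / parms[iTAU1], parms[iM1]);
    g2 = pow(tt / parms[iTAU2], parms[iM2]);
    return parms[iK] * (g1 / (1.0 + g1)) * (1.0 / (1.0 + g2)) + parms[iEMIN];
}

static void rhs(double t, const double *y, double *ydot, double *out)
{
    const double *p = parms;
    int fen = p[iFEN] > 0.5;
    int force = p[iFORCE] > 0.5;

    double V    = y[0], qtv = y[1], zeta = y[2], qav = y[3];
    double Par  = y[4], Pcu = y[5], Pcl  = y[6];
    double Psvc = y[7], Pivc = y[8], Pconf = y[9];
    double qsvc = y[10], qivc = y[11], qlpa = y[12], qrpa = y[13];
    double Pclpa = y[14], Pcrpa = y[15];
    double qfen = fen ? y[16] : 0.0;
    double Pcfen = fen ? y[17] : 0.0;

    double E = two_hill(t);
    double Prv = E * (V - p[iVREST]);

    /* tricuspid diode + inductor: smooth reverse-blocking resistance
     * (R_TV forward, R_TV + R_rev reverse, logistic blend over q_s) so the
     * right-hand side stays continuous for the stiff solver; the residual
     * reverse leak is ~drive/R_rev, a negligible fraction of the stroke */
    double R_rev = p[iCLAMP];          /* reverse-blocking resistance */
    double q_s = 5.0;                  /* blend width, mm^3/s */
    double arg = qtv / q_s;
    if (arg > 40.0) arg = 40.0;
    if (arg < -40.0) arg = -40.0;
    double sig = 1.0 / (1.0 + exp(arg));   /* ~1 when qtv << 0 */
    double Rtv_eff = force ? p[iRTV] : p[iRTV] + R_rev * sig;
    double dqtv = (p[iPRA] - Prv - Rtv_eff * qtv) / p[iITV];
    double qtv_fwd = qtv;

    /* aortic valve: opening-state dynamics + Bernoulli-inertance drop */
    double zc = zeta < 0.0 ? 0.0 : (zeta > 1.0 ? 1.0 : zeta);
    double dpv = Prv - Par;
    double dzeta = 0.0;
    if (force) {
        zc = 1.0;
    } else if (dpv > p[iPOPEN]) {
        dzeta = (1.0 - zc) * p[iKVO] * (dpv - p[iPOPEN]);
    } else if (dpv < -p[iPCLOSE]) {
        dzeta = zc * p[iKVC] * (dpv + p[iPCLOSE]);
    }
    double Aeff = (p[iMST] - p[iMRG]) * p[iAANN] * zc + p[iMRG] * p[iAANN];
    if (Aeff < 1e-6) Aeff = 1e-6;
    double B  = p[iRHO] / (2.0 * Aeff * Aeff);
    double Lv = p[iRHO] * p[iLEFF] / Aeff;
    double dqav = (dpv - B * qav * fabs(qav) - p[iKSLIN] * qav)
                  / (Lv + p[iIAR]);

    double dV = qtv_fwd - qav;

    /* aortic root node feeding the two systemic beds */
    double qubv = (Par - Pcu) / p[iWK + 0];
    double qlbv = (Par - Pcl) / p[iWK + 4];
    double dPar = (qav - qubv - qlbv) / p[iCAR];

    /* series systemic Windkessels discharging into the caval inlets */
    double qsvc_in = (Pcu - Psvc) / p[iWK + 2];
    double qivc_in = (Pcl - Pivc) / p[iWK + 6];
    double dPcu = (qubv - qsvc_in) / p[iWK + 1];
    double dPcl = (qlbv - qivc_in) / p[iWK + 5];

    /* junction nodes */
    double dPsvc  = (qsvc_in - qsvc) / p[iCNSVC];
    double dPivc  = (qivc_in - qivc - qfen) / p[iCNIVC];
    double dPconf = (qsvc + qivc - qlpa - qrpa) / p[iCNCONF];

    /* junction segments */
    double dqsvc = (Psvc - Pconf - p[iRSVC] * qsvc) / p[iLSVC];
    double dqivc = (Pivc - Pconf - p[iRIVC] * qivc) / p[iLIVC];

    /* pulmonary outlets through their Windkessels */
    double dqlpa = (Pconf - (p[iRLPA] + p[iWK + 8]) * qlpa - Pclpa)
                   / p[iLLPA];
    double dPclpa = (qlpa - (Pclpa - p[iWK + 11]) / p[iWK + 10])
                    / p[iWK + 9];
    double dqrpa = (Pconf - (p[iRRPA] + p[iWK + 12]) * qrpa - Pcrpa)
                   / p[iLRPA];
    double dPcrpa = (qrpa - (Pcrpa - p[iWK + 15]) / p[iWK + 14])
                    / p[iWK + 13];

    ydot[0] = dV;    ydot[1] = dqtv;  ydot[2] = dzeta; ydot[3] = dqav;
    ydot[4] = dPar;  ydot[5] = dPcu;  ydot[6] = dPcl;
    ydot[7] = dPsvc; ydot[8] = dPivc; ydot[9] = dPconf;
    ydot[10] = dqsvc; ydot[11] = dqivc; ydot[12] = dqlpa; ydot[13] = dqrpa;
    ydot[14] = dPclpa; ydot[15] = dPcrpa;

    if (fen) {
        ydot[16] = (Pivc - (p[iRFEN] + p[iWK + 16]) * qfen - Pcfen)
                   / p[iLFEN];
        ydot[17] = (qfen - (Pcfen - p[iWK + 19]) / p[iWK + 18])
                   / p[iWK + 17];
    }

    if (out != NULL) {
        out[0] = Prv;
        out[1] = E;
        out[2] = qsvc_in;                       /* SVC face flow */
        out[3] = qivc_in;                       /* IVC face flow */
        out[4] = Pclpa + p[iWK + 8]  * qlpa;    /* LPA face pressure */
        out[5] = Pcrpa + p[iWK + 12] * qrpa;    /* RPA face pressure */
        out[6] = fen ? Pcfen + p[iWK + 16] * qfen : 0.0;
        out[7] = qtv_fwd;
        out[8] = qfen;
    }
}

/* deSolve entry point */
void circ_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    if (ip[0] < NOUT) error("nout should be at least %d", NOUT);
    rhs(*t, y, ydot, yout);
}

/* .Call entry point for direct evaluation from R (testing / oracles) */
SEXP C_circ_rhs(SEXP st, SEXP sy, SEXP sparms)
{
    int i, n = length(sy);
    double yd[18], out[NOUT];
    SEXP ans, dy, ou, nms;

    if (length(sparms) != NPARMS)
        error("parameter vector must have length %d", NPARMS);
    for (i = 0; i < NPARMS; i++)
        parms[i] = REAL(sparms)[i];
    if (n != (parms[iFEN] > 0.5 ? 18 : 16))
        error("state vector has wrong length");

    rhs(REAL(st)[0], REAL(sy), yd, out);

    ans = PROTECT(allocVector(VECSXP, 2));
    dy = PROTECT(allocVector(REALSXP, n));
    ou = PROTECT(allocVector(REALSXP, NOUT));
    for (i = 0; i < n; i++) REAL(dy)[i] = yd[i];
    for (i = 0; i < NOUT; i++) REAL(ou)[i] = out[i];
    SET_VECTOR_ELT(ans, 0, dy);
    SET_VECTOR_ELT(ans, 1, ou);
    nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("ydot"));
    SET_STRING_ELT(nms, 1, mkChar("out"));
    setAttrib(ans, R_NamesSymbol, nms);
    UNPROTECT(4);
    return ans;
}
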